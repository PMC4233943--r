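---
title: "Global tractography with anatomical priors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global tractography with anatomical priors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtract)
```

## The problem

Streamline tractography reconstructs white-matter pathways from diffusion
MRI, but most reconstructed trajectories stop prematurely inside the white
matter (WM) and never reach the gray matter (GM), and every streamline
contributes equally, so the result is not quantitative. Both properties are
fatal for structural connectivity analysis: connections are defined between
cortical regions, and their strength should reflect how much signal the
pathway actually explains.

`gtract` addresses this with a *global* formulation. A whole-brain (or
whole-phantom) configuration of fibers is optimized jointly so that its
predicted diffusion attenuation best explains the measured data, under two
hard anatomical constraints baked into the fiber parameterization:

* each fiber is a Catmull-Rom spline with (by default) 7 control points;
* the two end control points must lie in labeled GM, all interior control
  points in WM.

Each fiber also carries a non-negative weight scaling its signal
contribution, so the optimized tractogram is quantitative by construction:
the *connection strength* between two regions is the sum of the weights of
the fibers joining them.

## Forward model

A spline is discretized into segments of equal arc length (2 mm by
default; the segment size should stay below the voxel size). A segment at
position $x_\mathrm{seg}$ with unit orientation $n_\mathrm{seg}$
contributes, at voxel center $x$ and gradient direction $n$ with b-value
$b$,

$$\rho_\mathrm{seg}(x, n) \;=\;
  e^{-b\, n^\top D_\mathrm{seg}\, n}\;
  e^{-\lVert x - x_\mathrm{seg}\rVert^2 / \sigma^2},$$

where $D_\mathrm{seg}$ is an axially symmetric diffusion tensor with
eigenvalues $[2.1;\,0.85;\,0.85]\ \mu\mathrm{m}^2/\mathrm{ms}$ (a value
appropriate for the FiberCup acquisition regime; configurable) rotated so
its principal axis follows $n_\mathrm{seg}$. The configuration prediction
is linear in the weights,
$\rho_M(x,n) = \sum_f w_f \sum_{\mathrm{seg} \in f} \rho_\mathrm{seg}(x,n)$,
and is scored against the measured attenuation $D(x,n) = S(x,n)/S_0(x)$ by
the L2 energy $E(M, D) = \lVert \rho_M - D \rVert_2^2$ over the
diffusion-weighted measurements.

Numerical choices:

* The spatial kernel width is $\sigma = 0.5$ **in voxel units**, so the
  kernel's voxel footprint is the same across acquisitions with different
  voxel sizes. The kernel is truncated at $3\sigma$, where its amplitude
  is below $1.3\times10^{-4}$; a cache audit (every 20,000 iterations by
  default) bounds the accumulated error of incremental energy updates and
  rebuilds the cache if the relative discrepancy exceeds $10^{-6}$.
* The tensor exponent uses the *measurement* direction against the
  segment-oriented tensor, $n^\top D_\mathrm{seg} n$. A per-segment
  constant exponent would carry no directional information and could not
  drive the optimization.
* b0 measurements are excluded from the energy: on the attenuation scale
  they are 1 by construction and carry no anisotropy information.
* The energy is evaluated over the **whole image**, not only the WM mask.
  Anatomical validity is checked at the control points only (if a control
  point leaves GM/WM the spline is rejected before any energy
  evaluation); a cubic can still bulge outside the white matter *between*
  control points, and a WM-restricted energy would make such excursions
  free. During development we observed the sampler exploiting exactly
  this: fibers folded through unmasked background and poached other
  bundles' signal at compensating weights. With the whole-image energy,
  off-tissue signal is penalized by the data everywhere.
* Free water: voxels outside the WM carry an isotropic attenuation
  $e^{-b\,d_\mathrm{iso}}$ with $d_\mathrm{iso} = 2.0\
  \mu\mathrm{m}^2/\mathrm{ms}$. The fitted model treats this as a *fixed,
  known baseline* added to the fiber prediction (`free_water_baseline()`),
  not as an estimated compartment; multi-compartment estimation is out of
  scope.

## Optimization

`gtract_fit()` runs Metropolis-Hastings sampling with simulated annealing
over both the weights and the control-point geometry. Four proposals are
drawn with fixed probabilities 40/40/15/5:

1. **change weight** - a new weight from a normal centered at the current
   one (scale 0.05), truncated to $[0, 1]$;
2. **move** - either one random control point or a whole-fiber
   translation (50/50), with an isotropic normal of scale a quarter voxel;
3. **add** - a fiber from the removed-fiber pool, or, when the pool is
   empty, a perturbed clone of a random active fiber;
4. **remove** - a random fiber, into the pool.

Candidates violating the anatomical constraints are rejected before any
energy evaluation, so every visited configuration satisfies the prior; such
rejections still advance the iteration counter and the temperature, keeping
the runtime bounded.

A second hard constraint enforces smoothness: the turn angle between
consecutive chords of the control polygon must stay below
`max_turn_deg` (90 degrees by default). Although a Catmull-Rom spline is
smooth in the differential sense, nothing stops a long Metropolis chain
from folding a fiber back on itself *inside* the white matter - the fold
doubles the fiber's segment density where it overlaps itself, its weight
halves to compensate, and the data term cannot see the difference. That
degeneracy silently halves connection strengths (we observed a 123 mm
fiber inhabiting a 44 mm bundle). True bundles on the phantom turn by at
most ~35 degrees per chord, a hairpin by ~180, so the 90-degree bound
separates them with a wide margin while leaving the geometry free to
adapt. A candidate with lower energy is always accepted;
otherwise it is accepted when $e^{-\Delta E / T} > u$, $u \sim U[0,1)$.

The temperature schedule is geometric, $T_k = T_0 (T_K/T_0)^{k/K}$, with
$T_0$ auto-calibrated to the standard deviation of $\Delta E$ over 100
probe proposals and $T_K = 10^{-3} T_0$; $K = 2 \times 10^5$ by default.
All stochasticity flows through R's RNG, so a seed makes runs bit
reproducible. Single-fiber changes update the cached prediction and energy
incrementally (only voxels within the truncation radius of the affected
segments are touched), which is what makes $2\times10^5$ iterations on a
$64 \times 64 \times 3 \times 65$ volume take well under a minute of CPU.

For planar single-slice data (such as the phantom below),
`sa_control(planar_moves = TRUE)` restricts geometry proposals to the
axial plane: the through-plane position of a fiber is not identifiable
there, because the $\sigma = 0.5$-voxel kernel does not reach the
neighboring slices and a through-plane shift merely rescales the fiber's
amplitude, which its weight absorbs.

## Library preparation

The optimizer needs an anatomically valid initial library. From any raw
candidate tractogram (TRK/TCK, or the built-in tracker):

1. **Extension and filtering** - endpoints not in GM are extended along
   the terminal tangent in half-voxel steps, up to one voxel; streamlines
   still not connecting GM to GM are discarded.
2. **Clustering** - greedy single-pass clustering under the
   minimum-average-direct-flip (MDF) distance with a 3 mm threshold on
   25-point resampled polylines; one representative (the flip-aligned
   pointwise mean) per cluster.
3. **Spline conversion** - each representative is reduced to 7 control
   points with rank-based Douglas-Peucker. Interior control points are
   kept at least two voxels (arc length) away from the endpoints so that
   points adjacent to the terminal GM region do not violate the
   interior-in-WM constraint.
4. **Initial weight** - a single common weight minimizing $E$ over the
   library. Because $E$ is an exact quadratic in a common scale, the
   closed-form minimizer
   $\langle\rho_1, D\rangle / \langle\rho_1, \rho_1\rangle$ of the
   unit-weight prediction $\rho_1$ is returned; a 64-point logarithmic
   grid scan over $[10^{-5}, 1]$ is retained as a cross-check and warns if
   its argmin is more than one grid step away.

The built-in tracker exists so that the whole pipeline is testable without
external tools. Minimum-attenuation direction following fails at crossings
(the summed two-tensor attenuation is minimized at the *bisector* of the
two fiber directions), so the tracker first deconvolves an in-plane
orientation distribution per voxel - Richardson-Lucy iterations with the
package's own single-tensor response over 90 axial orientation bins - and
follows the distribution's peaks, choosing at each step the peak nearest
the incoming direction within a 45-degree gate. Three details make it
robust under noise: a walker may *coast* straight for up to two steps
through a voxel whose distribution offers no gated peak; the tracking
domain is the WM mask dilated in-plane by one voxel (excluding voxels
adjacent to GM), because the spatial kernel spreads a bundle's signal
beyond its nominal mask and a strict mask truncates slightly drifting
walkers mid-bundle; and during spline conversion, control points that land
just outside the valid tissue (cluster means graze the mask boundary) are
projected onto the nearest valid voxel center before the hard constraints
are enforced (`project_to_tissue()`). It is deterministic and planar; a
candidate generator, not a general-purpose tracker.

## The synthetic phantom

`generate_phantom()` emulates a FiberCup-like dataset: a
$64 \times 64 \times 3$ slab at 3 mm isotropic resolution, 7 planar
bundles (straight, two orthogonal crossings, a U-shape, a shallow arc, and
a branching bundle) connecting 12 GM regions, 64 gradient directions at
$b = 1500\ \mathrm{s/mm^2}$ plus one b0. The noiseless signal is generated
with the package's own forward model from the true bundles (7-control-point
splines, generating weight 0.7 - chosen so that mid-tube attenuations land
in a physically plausible range of roughly 0.04-0.4), plus the free-water
background outside WM; Rician noise is applied on the attenuation scale
with $\sigma = 1/\mathrm{SNR}$ (SNR 20 by default, the regime of a decent
single-shell acquisition).

What the phantom does *not* emulate: scanner artifacts (eddy currents,
distortions, bias fields), partial-volume GM/WM boundaries, thick bundles
with internal fiber dispersion (each bundle is a single centerline with a
1-voxel tube), and 3D out-of-plane geometry. Passing the pipeline on this
phantom therefore demonstrates the correctness of the machinery - signal
prediction, constraint handling, optimization, scoring - not robustness to
the full complexity of acquired data.

The geometry constants (region radius 4.5 mm, tube radius 3 mm, the exact
curve equations in `default_bundles()`) are package choices recorded in
`phantom_spec()`; the topology (7 bundles, 12 regions, two crossing
configurations, one branching) is what matters for the evaluation.

## Evaluation

`evaluate_connectivity()` reproduces the quantitative evaluation chain:

* the **connection-strength matrix** (sum of fiber weights per region
  pair);
* **two-means classification** of strengths into valid/invalid bundles.
  The classification runs over *all* region pairs of the matrix including
  zero-strength ones - absent connections anchor the low-strength
  cluster, so a candidate set with no spurious bundle does not get its
  weakest true bundles discarded. In one dimension the optimal 2-means
  clusters are intervals, so the global optimum is computed exactly by
  scanning the sorted splits (iterative refinement from a fixed
  initialization can stall in a local optimum);
* **Tractometer-style scores**: VC/IC/NC percentages (per-fiber counts by
  default; weights optionally) and VB/IB bundle counts, against the known
  ground-truth pair list;
* **reproducibility**: the per-cell coefficient of variation (sample
  standard deviation over mean) of the connection-strength matrix across
  repeated runs, averaged over cells with nonzero mean.

On the default phantom the full pipeline (tracker, preparation,
$2\times10^5$ annealing iterations, classification) recovers all seven
bundles: VC 100%, IC 0%, NC 0%, VB 7, IB 0. NC is structurally zero after
preparation - that is the anatomical prior doing its job.

## Known limitations

* **Per-fiber strength identifiability.** With one cluster representative
  per bundle (which is what a 3 mm MDF threshold produces on 1-voxel-thick
  tubes), the optimized strength of a bundle is identified only to roughly
  $\pm 12\%$ at SNR 20: a sub-voxel displacement of a fiber lowers its
  per-voxel amplitude, its weight compensates, and the energy cost of the
  displacement is below the gain available from fitting the Rician noise
  (annealing runs reach energies *below* that of the true generating
  configuration). Weight estimation itself is highly reproducible - with
  geometry frozen, the run-to-run CV of connection strengths is about
  0.1% - so the spread is a property of the geometry-weight trade-off at
  this library size, not of the sampler. Libraries with many fibers per
  bundle average this jitter away; a single-representative desk-scale
  library cannot.
* Validity is checked at control points only; the whole-image energy
  discourages, but does not forbid, small excursions of the curve outside
  the WM between control points.
* The two radial tensor eigenvalues are treated as equal (their mean is
  used); a fully anisotropic radial profile would require an additional
  rotational degree of freedom that nothing in the data constrains.
* The number of control points is global (7 by default); per-fiber
  adaptive complexity is out of scope.

## Reproducing the numbers

`scripts/acceptance.R` re-runs the whole chain from scratch - phantom,
tracker, preparation, one full optimization with classification scores,
and ten repeated optimizations for the reproducibility CV - and writes the
resulting quantities as JSON. Problem sizes used there: the default
$64\times64\times3$ phantom, SNR 20, $2\times10^5$ iterations per run,
ten runs for the CV.
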