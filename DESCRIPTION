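Package: gtract
Title: Global Tractography with Anatomical Priors and Quantitative Fiber Weights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global tractography for diffusion MRI. Candidate fiber tracts are
    represented as weighted Catmull-Rom splines whose endpoints are constrained
    to gray matter and whose interior control points are constrained to white
    matter. Fiber geometry and non-negative per-fiber weights are optimized
    jointly by Metropolis-Hastings sampling with simulated annealing so that a
    multi-tensor forward model of the diffusion attenuation best explains the
    measured data. Includes a synthetic FiberCup-like phantom generator, TRK/TCK
    tractogram input/output, streamline library preparation (gray-matter
    extension, filtering, MDF clustering, initial weight calibration), and
    connectivity evaluation (connection-strength matrices, two-means bundle
    classification, Tractometer-style scores, reproducibility statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tools,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
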