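# Synthetic FiberCup-like phantom: a thin slab with 7 ground-truth bundles
# connecting 12 labeled gray-matter regions, plus a simulated diffusion
# acquisition (64 directions, b = 1500 s/mm^2) generated with the package's
# own forward model and Rician noise.

#' Evenly spread unit gradient directions
#'
#' Deterministic Fibonacci-hemisphere construction.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
make_gradient_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Gradient scheme for the synthetic phantom
#'
#' One b0 measurement followed by `n_dirs` diffusion-weighted directions at
#' a single shell.
#'
#' @param n_dirs number of diffusion-weighted directions (default 64).
#' @param bvalue shell b-value in s/mm^2 (default 1500).
#' @return A [gradient_scheme()].
#' @export
phantom_scheme <- function(n_dirs = 64, bvalue = 1500) {
  dirs <- rbind(c(0, 0, 0), make_gradient_dirs(n_dirs))
  gradient_scheme(dirs, c(0, rep(bvalue, n_dirs)))
}

# default planar bundle geometry: straight, crossing, U-shaped, and
# branching/kissing configurations in a 192 x 192 mm field of view
quad_bezier <- function(p0, p1, p2, n = 200) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * p1[2] + t^2 * p2[2])
}

#' Default ground-truth bundle geometry
#'
#' Seven planar centerlines connecting 12 distinct endpoint regions:
#' a straight bundle crossed at right angle by a second one, a U-shaped
#' bundle, a second crossing pair, a shallow arc, and a branching bundle
#' sharing one endpoint region with the arc and one with the U.
#'
#' @return list of bundle descriptors (`rois`, in-plane `points` in mm).
#' @export
default_bundles <- function() {
  lin <- function(a, b, n = 200) {
    t <- seq(0, 1, length.out = n)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  arc <- function(center, radius, from, to, n = 200) {
    t <- seq(from, to, length.out = n)
    cbind(center[1] + radius * cos(t), center[2] + radius * sin(t))
  }
  list(
    list(rois = c(1L, 2L), points = lin(c(24, 30), c(166, 30))),
    list(rois = c(3L, 4L), points = lin(c(95, 8), c(95, 52))),
    list(rois = c(5L, 6L), points = arc(c(30, 90), 30, -pi / 2, pi / 2)),
    list(rois = c(7L, 8L), points = lin(c(120, 70), c(170, 120))),
    list(rois = c(9L, 10L), points = lin(c(170, 70), c(120, 120))),
    list(rois = c(11L, 12L), points = quad_bezier(c(60, 160), c(105, 138),
                                                  c(150, 160))),
    list(rois = c(11L, 6L), points = quad_bezier(c(60, 160), c(30, 155),
                                                 c(30, 120)))
  )
}

#' Phantom specification
#'
#' Defines the study conditions of the synthetic dataset: a 64 x 64 x 3
#' slab at 3 mm isotropic resolution, 7 bundles between 12 gray-matter
#' regions, 64 gradient directions at b = 1500 s/mm^2, and Rician noise at
#' the given SNR.
#'
#' @param dims grid shape (default `c(64, 64, 3)`).
#' @param voxel_size voxel edge in mm (default 3).
#' @param bundles list of bundle descriptors (default [default_bundles()]).
#' @param n_dirs,bvalue acquisition scheme (defaults 64 and 1500).
#' @param snr signal-to-noise ratio of the Rician noise on the attenuation
#'   scale (default 20); `Inf` for noiseless data.
#' @param weight generating weight of every bundle (default 0.7).
#' @param roi_radius gray-matter region radius in mm (default 4.5).
#' @param tube_radius white-matter tube radius around each centerline in mm
#'   (default 3).
#' @param d_iso isotropic free-water diffusivity outside the white matter,
#'   um^2/ms (default 2.0; set 0 to disable the background compartment).
#' @param seed random seed for the noise (default 1).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 3), voxel_size = 3,
                         bundles = default_bundles(), n_dirs = 64,
                         bvalue = 1500, snr = 20, weight = 0.7,
                         roi_radius = 4.5, tube_radius = 3, d_iso = 2.0,
                         seed = 1) {
  rois <- t(vapply(bundles, function(b) b$rois, integer(2)))
  if (any(rois[, 1] == rois[, 2]))
    stop("each bundle must connect two distinct regions")
  key <- apply(rois, 1, function(p) paste(sort(p), collapse = "-"))
  if (anyDuplicated(key)) stop("bundle region pairs must be unique")
  structure(list(dims = as.integer(dims), voxel_size = voxel_size,
                 bundles = bundles, n_dirs = n_dirs, bvalue = bvalue,
                 snr = snr, weight = weight, roi_radius = roi_radius,
                 tube_radius = tube_radius, d_iso = d_iso, seed = seed),
            class = "phantom_spec")
}

#' Build the phantom tissue model and ground truth
#'
#' Paints a gray-matter disc at each bundle endpoint and a white-matter tube
#' of the given radius around each centerline (bundles live in the middle
#' slice of the slab). Every centerline is converted to a 7-control-point
#' Catmull-Rom spline; the tube follows the spline so that the generated
#' signal ridge and the mask agree.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tissue` (a [tissue_model()]) and `truth` (bundle ROI
#'   pairs, centerlines, spline control points, generating weights, region
#'   centers).
#' @export
build_phantom <- function(spec = phantom_spec()) {
  d <- spec$dims
  vs <- spec$voxel_size
  z_mid <- floor(d[3] / 2)           # voxel index of the bundle slice
  z_world <- z_mid * vs
  affine <- diag(c(vs, vs, vs, 1))

  to3d <- function(p2) cbind(p2, z_world)
  centerlines <- lapply(spec$bundles, function(b) to3d(b$points))
  protect <- spec$roi_radius + vs / 2
  splines <- lapply(centerlines, polyline_to_spline, n_control = 7,
                    n_resample = 25, protect_mm = protect)
  pairs <- t(vapply(spec$bundles, function(b) b$rois, integer(2)))
  roi_ids <- sort(unique(as.vector(pairs)))

  # region centers = centerline endpoints
  centers <- matrix(NA_real_, max(roi_ids), 2)
  for (i in seq_along(spec$bundles)) {
    ends <- spec$bundles[[i]]$points[c(1, nrow(spec$bundles[[i]]$points)), ]
    for (k in 1:2) {
      id <- pairs[i, k]
      if (any(is.na(centers[id, ]))) centers[id, ] <- ends[k, ]
      else if (max(abs(centers[id, ] - ends[k, ])) > 1e-6)
        stop("region ", id, " referenced with inconsistent endpoint positions")
    }
  }

  gx <- (seq_len(d[1]) - 1) * vs
  gy <- (seq_len(d[2]) - 1) * vs
  gm2 <- matrix(0L, d[1], d[2])
  for (id in roi_ids) {
    dx <- outer(gx - centers[id, 1], rep(1, d[2]))
    dy <- outer(rep(1, d[1]), gy - centers[id, 2])
    hit <- dx^2 + dy^2 <= spec$roi_radius^2
    clash <- hit & gm2 != 0L & gm2 != id
    if (any(clash)) stop("overlapping region labels: ", id, " and ",
                         gm2[which(clash)[1]])
    gm2[hit] <- id
  }

  wm2 <- matrix(FALSE, d[1], d[2])
  for (ctrl in splines) {
    pts <- catmull_rom_evaluate(ctrl, seq(0, 1, length.out = 400))
    for (j in seq_len(nrow(pts))) {
      px <- pts[j, 1]; py <- pts[j, 2]
      rx <- which(abs(gx - px) <= spec$tube_radius)
      ry <- which(abs(gy - py) <= spec$tube_radius)
      for (ix in rx) for (iy in ry)
        if ((gx[ix] - px)^2 + (gy[iy] - py)^2 <= spec$tube_radius^2)
          wm2[ix, iy] <- TRUE
    }
  }
  wm2[gm2 != 0L] <- FALSE

  gm_labels <- array(0L, d)
  wm_mask <- array(FALSE, d)
  gm_labels[, , z_mid + 1] <- gm2
  wm_mask[, , z_mid + 1] <- wm2
  tissue <- tissue_model(gm_labels, wm_mask, rep(vs, 3), affine)

  ok <- check_anatomical_validity(spline_set(splines), tissue)
  if (!all(ok))
    stop("internal inconsistency: ground-truth spline(s) ",
         paste(which(!ok), collapse = ", "), " violate the tissue model")

  truth <- structure(list(pairs = pairs, centerlines = centerlines,
                          splines = splines,
                          weights = rep(spec$weight, length(splines)),
                          roi_centers = centers, n_rois = length(roi_ids)),
                     class = "ground_truth")
  list(tissue = tissue, truth = truth)
}

#' Simulate the diffusion acquisition of a phantom
#'
#' The noiseless attenuation is the forward-model prediction of the true
#' bundles (discretized as splines with their generating weights). Voxels
#' outside the white matter additionally carry an isotropic free-water
#' attenuation `exp(-b * d_iso)`. Rician noise with sigma = 1/SNR is applied
#' on the attenuation scale of the diffusion-weighted measurements; b0
#' entries are exactly 1 by construction (the data are already normalized).
#'
#' @param truth,tissue output of [build_phantom()].
#' @param scheme a [gradient_scheme()]; default [phantom_scheme()].
#' @param params a [forward_params()].
#' @param snr signal-to-noise ratio; `Inf` for noiseless.
#' @param d_iso free-water diffusivity in um^2/ms outside WM (0 disables).
#' @param seed random seed for the noise.
#' @return An [attenuation_volume()].
#' @export
simulate_dwi <- function(truth, tissue, scheme = phantom_scheme(),
                         params = forward_params(), snr = 20, d_iso = 2.0,
                         seed = 1) {
  d <- dim(tissue$gm_labels)
  G <- nrow(scheme$directions)
  dw <- which(!scheme$b0_mask)
  atten <- array(0, c(d, G))
  atten[, , , scheme$b0_mask] <- 1

  if (length(truth$splines)) {
    fibers <- spline_set(truth$splines, truth$weights)
    pred <- predict_signal(fibers, tissue, scheme, params)
  } else {
    pred <- array(0, c(d, length(dw)))
  }
  bg <- !tissue$wm_mask
  for (k in seq_along(dw)) {
    sl <- pred[, , , k]
    if (d_iso > 0)
      sl[bg] <- sl[bg] + exp(-scheme$bvalues[dw[k]] * 1e-3 * d_iso)
    atten[, , , dw[k]] <- sl
  }

  if (is.finite(snr)) {
    if (snr <= 0) stop("snr must be > 0 (or Inf for noiseless)")
    set.seed(seed)
    sigma <- 1 / snr
    nvox <- prod(d) * length(dw)
    a <- atten[, , , dw, drop = FALSE]
    noisy <- sqrt((a + array(rnorm(nvox, 0, sigma), dim(a)))^2 +
                  array(rnorm(nvox, 0, sigma), dim(a))^2)
    atten[, , , dw] <- noisy
  }
  attenuation_volume(atten, scheme, tissue$affine)
}

#' Generate a complete phantom dataset
#'
#' Convenience wrapper: builds the tissue model and ground truth, then
#' simulates the acquisition.
#'
#' @param spec a [phantom_spec()].
#' @param params a [forward_params()].
#' @return list with `tissue`, `truth`, `dwi`, `scheme`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             params = forward_params()) {
  ph <- build_phantom(spec)
  scheme <- phantom_scheme(spec$n_dirs, spec$bvalue)
  dwi <- simulate_dwi(ph$truth, ph$tissue, scheme, params, snr = spec$snr,
                      d_iso = spec$d_iso, seed = spec$seed)
  list(tissue = ph$tissue, truth = ph$truth, dwi = dwi, scheme = scheme,
       spec = spec)
}
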