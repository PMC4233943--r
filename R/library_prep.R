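# Library preparation: endpoint extension into gray matter, anatomical
# filtering, MDF (minimum-average-direct-flip) clustering, and initial
# weight calibration.

#' Extend a streamline's endpoints into gray matter
#'
#' Each endpoint not already in GM is pushed along the terminal tangent
#' direction in steps of half a voxel, up to `max_extension_mm`. Returns the
#' (possibly) extended streamline, or `NULL` (rejection) if either endpoint
#' cannot reach GM: endpoints stopping more than a voxel short of GM are
#' excluded from the library.
#'
#' @param streamline n x 3 matrix (world mm), n >= 2.
#' @param tissue a [tissue_model()].
#' @param max_extension_mm maximum extension per endpoint; default one voxel.
#' @return Extended matrix, or `NULL` if rejected.
#' @export
extend_to_gm <- function(streamline, tissue,
                         max_extension_mm = min(tissue$voxel_size)) {
  s <- as_point_matrix(streamline)
  step <- min(tissue$voxel_size) / 2
  extend_end <- function(pts, head) {
    if (head) pts <- pts[nrow(pts):1, , drop = FALSE]
    n <- nrow(pts)
    if (classify_point(pts[n, ], tissue) > 0)
      return(if (head) pts[n:1, , drop = FALSE] else pts)
    dir <- pts[n, ] - pts[n - 1, ]
    nd <- sqrt(sum(dir^2))
    if (nd == 0) return(NULL)
    dir <- dir / nd
    k <- 1
    while (k * step <= max_extension_mm + 1e-9) {
      cand <- pts[n, ] + k * step * dir
      if (classify_point(cand, tissue) > 0) {
        out <- rbind(pts, cand)
        return(if (head) out[nrow(out):1, , drop = FALSE] else out)
      }
      k <- k + 1
    }
    NULL
  }
  s <- extend_end(s, head = FALSE)
  if (is.null(s)) return(NULL)
  extend_end(s, head = TRUE)
}

#' Filter a tractogram to anatomically valid streamlines
#'
#' Applies [extend_to_gm()] to every streamline and keeps exactly those whose
#' (possibly extended) endpoints both classify as gray matter.
#'
#' @param tract a [tractogram()].
#' @param tissue a [tissue_model()].
#' @param max_extension_mm see [extend_to_gm()].
#' @return A filtered [tractogram()].
#' @export
filter_library <- function(tract, tissue,
                           max_extension_mm = min(tissue$voxel_size)) {
  kept <- list()
  for (s in tract$streamlines) {
    e <- extend_to_gm(s, tissue, max_extension_mm)
    if (!is.null(e)) kept[[length(kept) + 1]] <- e
  }
  if (!length(kept)) {
    warning("no streamline survived anatomical filtering")
    return(structure(list(streamlines = list(), weights = NULL,
                          affine = tract$affine), class = "tractogram"))
  }
  tractogram(kept, affine = tract$affine)
}

#' Minimum-average-direct-flip distance between two streamlines
#'
#' Both streamlines must have the same number of points (resample first).
#' The MDF distance is the smaller of the mean pointwise distance in direct
#' and in flipped order, which makes it invariant to streamline orientation.
#'
#' @param a,b n x 3 matrices with equal n.
#' @return scalar distance in mm.
#' @export
mdf_distance <- function(a, b) {
  a <- as_point_matrix(a); b <- as_point_matrix(b)
  if (nrow(a) != nrow(b)) stop("streamlines must have equal point counts")
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[nrow(b):1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' Cluster streamlines under the MDF distance
#'
#' Greedy single-pass (QuickBundles-style) clustering: every streamline is
#' resampled to `n_points` equidistant points and assigned to the nearest
#' existing cluster if its MDF distance to the cluster representative is
#' below `threshold`, otherwise it founds a new cluster. The representative
#' is the pointwise mean of the members after flip alignment. Duplicates
#' (MDF 0) always merge.
#'
#' @param tract a [tractogram()].
#' @param threshold MDF merge threshold in mm (default 3).
#' @param n_points resampling density (default 25).
#' @return A [tractogram()] of cluster representatives, with attribute
#'   `cluster_sizes`.
#' @export
cluster_streamlines <- function(tract, threshold = 3, n_points = 25) {
  if (threshold <= 0) stop("threshold must be > 0")
  reps <- list()    # running mean polyline per cluster
  sizes <- integer()
  for (s in tract$streamlines) {
    r <- resample_polyline(s, n_points)
    best <- NA_integer_; best_d <- Inf; best_flip <- FALSE
    for (k in seq_along(reps)) {
      direct <- mean(sqrt(rowSums((r - reps[[k]])^2)))
      flipped <- mean(sqrt(rowSums((r - reps[[k]][n_points:1, ])^2)))
      d <- min(direct, flipped)
      if (d < best_d) { best_d <- d; best <- k; best_flip <- flipped < direct }
    }
    if (!is.na(best) && best_d < threshold) {
      if (best_flip) r <- r[n_points:1, , drop = FALSE]
      m <- sizes[best]
      reps[[best]] <- (reps[[best]] * m + r) / (m + 1)
      sizes[best] <- m + 1L
    } else {
      reps[[length(reps) + 1]] <- r
      sizes <- c(sizes, 1L)
    }
  }
  out <- tractogram(reps, affine = tract$affine)
  attr(out, "cluster_sizes") <- sizes
  out
}

#' Calibrate the common initial fiber weight
#'
#' Finds the single weight w, shared by every fiber, that minimizes the
#' data-fit energy E(M_w, D). Because the prediction is linear in the common
#' weight, E is an exact quadratic in w and the minimizer has the closed
#' form `<rho_1, D> / <rho_1, rho_1>` with rho_1 the unit-weight prediction;
#' that value (clamped to (0, 1]) is returned. A scan over a logarithmic
#' grid of 64 weights in [1e-5, 1] is used as a cross-check and triggers a
#' warning if its argmin is more than one grid step away.
#'
#' @param fibers a [spline_set()] (weights ignored).
#' @param dwi an [attenuation_volume()].
#' @param tissue a [tissue_model()] (supplies the free-water background
#'   outside the white matter, which is subtracted from the data).
#' @param params a [forward_params()].
#' @param d_iso free-water diffusivity of the background, um^2/ms
#'   (default 2.0; 0 disables the background).
#' @param grid_n,grid_range log-grid resolution for the cross-check.
#' @return The calibrated weight, with the grid scan attached as attribute
#'   `scan` (data.frame of weight and energy).
#' @export
calibrate_initial_weight <- function(fibers, dwi, tissue,
                                     params = forward_params(), d_iso = 2.0,
                                     grid_n = 64, grid_range = c(1e-5, 1)) {
  if (!length(fibers$control)) stop("empty fiber library")
  unit <- spline_set(fibers$control, rep(1, length(fibers$control)))
  rho1 <- predict_signal(unit, dwi, dwi$scheme, params)
  mask <- dwi$mask
  dw <- attr(rho1, "dw_index")
  obs <- array(dwi$data[, , , dw, drop = FALSE], dim(rho1))
  if (d_iso > 0)
    obs <- obs - free_water_baseline(tissue, dwi$scheme, d_iso)
  m4 <- as.vector(array(mask, dim(obs)))
  r <- as.vector(rho1)[m4]
  d <- as.vector(obs)[m4]
  rr <- sum(r * r)
  if (rr <= 0) stop("all-zero prediction: no signal-bearing fiber")
  w_star <- sum(r * d) / rr
  w_star <- min(max(w_star, .Machine$double.eps), 1)
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_n))
  e_grid <- vapply(grid, function(w) sum((w * r - d)^2), 0)
  w_grid <- grid[which.min(e_grid)]
  step_ratio <- (grid_range[2] / grid_range[1])^(1 / (grid_n - 1))
  if (w_grid / w_star > step_ratio^1.5 || w_star / w_grid > step_ratio^1.5)
    warning("grid argmin (", signif(w_grid, 4),
            ") disagrees with closed-form minimizer (", signif(w_star, 4),
            ") by more than one grid step")
  structure(w_star, scan = data.frame(weight = grid, energy = e_grid))
}

#' Prepare an initial spline library from a raw tractogram
#'
#' Full preparation pipeline: anatomical filtering (with endpoint
#' extension), MDF clustering, conversion of the cluster representatives to
#' 7-control-point splines, validity screening, and initial weight
#' calibration.
#'
#' @param tract a [tractogram()] of candidate streamlines.
#' @param dwi an [attenuation_volume()].
#' @param tissue a [tissue_model()].
#' @param params a [forward_params()].
#' @param threshold,n_points clustering parameters (defaults 3 mm, 25).
#' @param n_control control points per spline (default 7).
#' @param protect_mm arc margin keeping interior control points away from
#'   the terminal gray-matter region; default twice the voxel size.
#' @param d_iso free-water diffusivity passed to
#'   [calibrate_initial_weight()].
#' @param max_turn_deg drop splines whose control polygon turns more
#'   sharply than this (default 90, matching the optimizer's smoothness
#'   constraint).
#' @return A [spline_set()] with every weight set to the calibrated common
#'   initial weight.
#' @export
prepare_library <- function(tract, dwi, tissue, params = forward_params(),
                            threshold = 3, n_points = 25, n_control = 7,
                            protect_mm = 2 * min(tissue$voxel_size),
                            d_iso = 2.0, max_turn_deg = 90) {
  filtered <- filter_library(tract, tissue)
  if (!length(filtered$streamlines)) stop("empty library after filtering")
  clustered <- cluster_streamlines(filtered, threshold, n_points)
  ctrl <- lapply(clustered$streamlines, polyline_to_spline,
                 n_control = n_control, n_resample = n_points,
                 protect_mm = protect_mm)
  # cluster means can graze the mask boundary; snap control points onto
  # the valid tissue before enforcing the hard constraints
  ctrl <- lapply(ctrl, project_to_tissue, tissue = tissue)
  ok <- check_anatomical_validity(spline_set(ctrl), tissue) &
        max_chord_turn(spline_set(ctrl)) <= max_turn_deg
  if (!any(ok)) stop("no anatomically valid spline after conversion")
  if (!all(ok))
    message(sum(!ok), " spline(s) dropped for violating the tissue model")
  ctrl <- ctrl[ok]
  fibers <- spline_set(ctrl)
  w0 <- calibrate_initial_weight(fibers, dwi, tissue, params, d_iso = d_iso)
  spline_set(ctrl, rep(as.numeric(w0), length(ctrl)))
}
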