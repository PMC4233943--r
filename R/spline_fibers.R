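# Spline fiber model: polyline -> 7-control-point Catmull-Rom conversion,
# equal-arc-length segment discretization, anatomical validity.

#' Resample a polyline to equidistant points
#'
#' Arc-length-uniform resampling; the endpoints are preserved exactly.
#'
#' @param points n x 3 matrix of ordered coordinates (world mm).
#' @param n_points number of output points (>= 2).
#' @return n_points x 3 matrix.
#' @export
resample_polyline <- function(points, n_points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2) stop("polyline needs at least 2 points")
  if (n_points < 2) stop("n_points must be >= 2")
  seg <- sqrt(rowSums(diff(points)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  if (L <= 0) stop("polyline has zero length")
  s <- seq(0, L, length.out = n_points)
  out <- sapply(1:3, function(d) approx(cum, points[, d], xout = s,
                                        ties = "ordered")$y)
  matrix(out, ncol = 3)
}

polyline_length <- function(points) {
  points <- as_point_matrix(points)
  sum(sqrt(rowSums(diff(points)^2)))
}

# perpendicular distance of points to the infinite line through a and b
line_distance <- function(points, a, b) {
  ab <- b - a
  nab2 <- sum(ab^2)
  rel <- sweep(points, 2, a)
  if (nab2 < 1e-24) return(sqrt(rowSums(rel^2)))
  tproj <- as.vector(rel %*% ab) / nab2
  foot <- outer(tproj, ab)
  sqrt(rowSums((rel - foot)^2))
}

#' Rank-based Douglas-Peucker polyline reduction
#'
#' Reduces a polyline to exactly `n_target` points by iteratively keeping the
#' point with the largest perpendicular deviation from the current
#' piecewise-linear approximation (equivalent to classic Douglas-Peucker run
#' at the tolerance that retains exactly `n_target` points). The output is a
#' subsequence of the input that always contains both endpoints. If the input
#' has fewer than `n_target` points it is first padded by inserting points at
#' the arc midpoints of the longest segments.
#'
#' `protect_mm` excludes interior points closer than that arc distance to
#' either endpoint from selection. This keeps interior control points away
#' from the terminal gray-matter region, where the anatomical prior requires
#' them to lie in white matter.
#'
#' @param points n x 3 matrix of ordered coordinates.
#' @param n_target number of points to keep (>= 2).
#' @param protect_mm arc-length margin near the endpoints (default 0).
#' @return n_target x 3 matrix.
#' @export
douglas_peucker_reduce <- function(points, n_target, protect_mm = 0) {
  points <- as_point_matrix(points)
  if (n_target < 2) stop("n_target must be >= 2")
  while (nrow(points) < n_target) {
    seg <- sqrt(rowSums(diff(points)^2))
    j <- which.max(seg)
    mid <- (points[j, ] + points[j + 1, ]) / 2
    points <- rbind(points[seq_len(j), , drop = FALSE], mid,
                    points[(j + 1):nrow(points), , drop = FALSE])
    message("polyline shorter than n_target: padded with arc midpoints")
  }
  n <- nrow(points)
  arc <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  L <- arc[n]
  eligible <- rep(TRUE, n)
  if (protect_mm > 0) {
    eligible <- arc >= protect_mm & (L - arc) >= protect_mm
    eligible[c(1, n)] <- TRUE
    if (sum(eligible) < n_target) eligible <- rep(TRUE, n)
  }
  kept <- c(1L, n)
  while (length(kept) < n_target) {
    kept <- sort(kept)
    best_d <- -1
    best_j <- NA_integer_
    longest_gap <- -1
    gap_j <- NA_integer_
    for (k in seq_len(length(kept) - 1)) {
      a <- kept[k]; b <- kept[k + 1]
      if (b - a < 2) next
      cand <- seq.int(a + 1, b - 1)
      cand <- cand[eligible[cand]]
      if (!length(cand)) next
      dists <- line_distance(points[cand, , drop = FALSE],
                             points[a, ], points[b, ])
      jloc <- which.max(dists)
      if (dists[jloc] > best_d) {
        best_d <- dists[jloc]
        best_j <- cand[jloc]
      }
      if (arc[b] - arc[a] > longest_gap) {
        longest_gap <- arc[b] - arc[a]
        # arc midpoint of the widest gap: tie-break for flat stretches
        gap_j <- cand[which.min(abs(arc[cand] - (arc[a] + arc[b]) / 2))]
      }
    }
    if (is.na(best_j)) stop("cannot reduce: not enough selectable points")
    kept <- c(kept, if (best_d > 1e-12) best_j else gap_j)
  }
  points[sort(kept), , drop = FALSE]
}

#' Spline fiber set
#'
#' The unit of optimization: each fiber is a Catmull-Rom spline given by its
#' control points (7 by default) plus one non-negative weight scaling its
#' contribution to the predicted diffusion signal.
#'
#' @param control list of control-point matrices (n_control x 3, world mm).
#' @param weights numeric vector of non-negative fiber weights (default 0).
#' @return An object of class `spline_set`.
#' @export
spline_set <- function(control, weights = NULL) {
  if (is.matrix(control)) control <- list(control)
  control <- lapply(control, as_point_matrix)
  nc <- vapply(control, nrow, 0L)
  if (any(nc < 2)) stop("each fiber needs at least 2 control points")
  if (is.null(weights)) weights <- rep(0, length(control))
  if (length(weights) != length(control))
    stop("one weight per fiber required")
  if (any(weights < 0)) stop("weights must be >= 0")
  structure(list(control = control, weights = as.numeric(weights)),
            class = "spline_set")
}

#' @export
print.spline_set <- function(x, ...) {
  cat("Spline fiber set:", length(x$control), "fibers")
  if (length(x$weights))
    cat(", weights in [", signif(min(x$weights), 3), ",",
        signif(max(x$weights), 3), "]")
  cat("\n")
  invisible(x)
}

#' @export
length.spline_set <- function(x) length(x$control)

#' Evaluate a Catmull-Rom spline
#'
#' Uniform parameterization with duplicated end control points, so the curve
#' passes through every control point: `t = i/(n-1)` returns control point
#' `i` exactly (0-based). `t` outside `[0, 1]` is clamped.
#'
#' @param control n x 3 matrix of control points (n >= 2).
#' @param t numeric vector of curve parameters in `[0, 1]`.
#' @return length(t) x 3 matrix of points on the curve.
#' @export
catmull_rom_evaluate <- function(control, t) {
  control <- as_point_matrix(control)
  if (nrow(control) < 2) stop("need at least 2 control points")
  cpp_cr_eval(control, as.numeric(t))
}

#' Discretize a spline into equal-arc-length segments
#'
#' The spline arc length is estimated by dense sampling; the curve is cut
#' into `ceiling(L / segment_length)` pieces of equal arc length. Each
#' segment carries its curve midpoint, the unit chord direction, and its
#' length. A spline shorter than one segment yields a single segment
#' spanning it.
#'
#' @param control n x 3 control-point matrix (or a single-fiber
#'   [spline_set()]).
#' @param segment_length target segment length in mm (default 2, which should
#'   stay below the voxel size).
#' @return data.frame with columns `mx,my,mz` (midpoint), `dx,dy,dz`
#'   (unit direction) and `length`.
#' @export
discretize <- function(control, segment_length = 2) {
  if (inherits(control, "spline_set")) {
    if (length(control$control) != 1)
      stop("discretize() expects a single fiber")
    control <- control$control[[1]]
  }
  control <- as_point_matrix(control)
  if (segment_length <= 0) stop("segment_length must be > 0")
  s <- cpp_discretize(control, segment_length)
  data.frame(mx = s$mid[, 1], my = s$mid[, 2], mz = s$mid[, 3],
             dx = s$dir[, 1], dy = s$dir[, 2], dz = s$dir[, 3],
             length = s$length)
}

#' Anatomical validity of a spline fiber
#'
#' TRUE iff the two end control points classify as gray matter and every
#' interior control point classifies as white matter. Checking the control
#' points (rather than the full curve) is the model's own approximation: a
#' cubic can bulge slightly outside the region spanned by its control points.
#'
#' @param fibers a control-point matrix or a [spline_set()].
#' @param tissue a [tissue_model()].
#' @return Logical vector, one entry per fiber.
#' @export
check_anatomical_validity <- function(fibers, tissue) {
  ctrl <- if (inherits(fibers, "spline_set")) fibers$control
          else list(as_point_matrix(fibers))
  vapply(ctrl, function(C) {
    cls <- classify_point(C, tissue)
    n <- length(cls)
    cls[1] > 0 && cls[n] > 0 && all(cls[-c(1, n)] == GT_WM)
  }, logical(1))
}

#' Convert a polyline to a Catmull-Rom spline fiber
#'
#' Resamples the polyline to `n_resample` equidistant points, then reduces
#' them to `n_control` control points with rank-based Douglas-Peucker.
#'
#' @param points polyline matrix (world mm).
#' @param n_control number of control points (default 7).
#' @param n_resample resampling density before reduction (default 25).
#' @param protect_mm see [douglas_peucker_reduce()].
#' @return n_control x 3 control-point matrix.
#' @export
polyline_to_spline <- function(points, n_control = 7, n_resample = 25,
                               protect_mm = 0) {
  pts <- resample_polyline(points, max(n_resample, n_control))
  douglas_peucker_reduce(pts, n_control, protect_mm = protect_mm)
}

#' Maximum turn angle between consecutive control-point chords
#'
#' Geometric smoothness measure of a spline fiber: the largest angle (in
#' degrees) between successive chords of the control polygon. Hairpin
#' folds show up as turns approaching 180 degrees. The sampler rejects
#' candidates exceeding `sa_control()$max_turn_deg`.
#'
#' @param control n x 3 control-point matrix or a [spline_set()].
#' @return Numeric vector of maximum turn angles, one per fiber.
#' @export
max_chord_turn <- function(control) {
  ctrl <- if (inherits(control, "spline_set")) control$control
          else list(as_point_matrix(control))
  vapply(ctrl, function(C) {
    ch <- diff(C)
    nrm <- sqrt(rowSums(ch^2))
    ch <- ch[nrm > 1e-12, , drop = FALSE] / nrm[nrm > 1e-12]
    if (nrow(ch) < 2) return(0)
    dots <- pmin(pmax(rowSums(ch[-nrow(ch), , drop = FALSE] *
                              ch[-1, , drop = FALSE]), -1), 1)
    max(acos(dots)) * 180 / pi
  }, 0)
}

#' Project control points onto the anatomically valid tissue
#'
#' Moves each end control point not already in gray matter to the nearest
#' gray-matter voxel center, and each interior control point not already in
#' white matter to the nearest white-matter voxel center, searching within
#' `max_mm`. Points with no valid voxel in range are left unchanged (the
#' fiber will then fail [check_anatomical_validity()]). Used when converting
#' streamlines whose polylines graze the mask boundary into hard-constraint
#' spline fibers.
#'
#' @param control n x 3 control-point matrix.
#' @param tissue a [tissue_model()].
#' @param max_mm search radius in mm (default twice the voxel size).
#' @return The projected control-point matrix.
#' @export
project_to_tissue <- function(control, tissue,
                              max_mm = 2 * min(tissue$voxel_size)) {
  control <- as_point_matrix(control)
  n <- nrow(control)
  cls <- classify_point(control, tissue)
  d <- dim(tissue$gm_labels)
  for (i in seq_len(n)) {
    want_gm <- i == 1 || i == n
    ok <- if (want_gm) cls[i] > 0 else cls[i] == GT_WM
    if (ok) next
    v <- world_to_voxel(control[i, , drop = FALSE], tissue$affine)
    r <- ceiling(max_mm / min(tissue$voxel_size))
    lo <- pmax(floor(v) - r, 0)
    hi <- pmin(ceiling(v) + r, d - 1)
    if (any(lo > hi)) next
    cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                  z = lo[3]:hi[3]))
    lin <- 1 + cand[, 1] + d[1] * (cand[, 2] + d[2] * cand[, 3])
    good <- if (want_gm) tissue$gm_labels[lin] > 0 else tissue$wm_mask[lin]
    if (!any(good)) next
    centers <- voxel_to_world(cand[good, , drop = FALSE], tissue$affine)
    dist <- sqrt(rowSums(sweep(centers, 2, control[i, ])^2))
    j <- which.min(dist)
    if (dist[j] <= max_mm) control[i, ] <- centers[j, ]
  }
  control
}

#' Densely sample every fiber of a spline set
#'
#' @param fibers a [spline_set()].
#' @param step sampling step along the curve in mm (default 0.5).
#' @return list of polyline matrices.
#' @export
sample_splines <- function(fibers, step = 0.5) {
  lapply(fibers$control, function(C) {
    L <- polyline_length(catmull_rom_evaluate(C, seq(0, 1, length.out = 200)))
    n <- max(2, ceiling(L / step) + 1)
    catmull_rom_evaluate(C, seq(0, 1, length.out = n))
  })
}
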