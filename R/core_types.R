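#' @useDynLib gtract, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd approx setNames coef fitted
#'   residuals simulate
#' @importFrom utils write.csv read.csv read.table packageVersion
#' @importFrom graphics plot
NULL

#' Tissue class codes
#'
#' [classify_point()] returns an integer per point: a positive value is a
#' gray-matter region label, `GT_WM` (-1) marks white matter and
#' `GT_OUTSIDE` (0) marks everything else (background or off the grid).
#'
#' @export
GT_WM <- -1L

#' @rdname GT_WM
#' @export
GT_OUTSIDE <- 0L

#' Diffusion gradient scheme
#'
#' Bundles the unit gradient directions with their b-values. Entries with
#' b-value at or below `b0_threshold` are flagged as non-diffusion-weighted
#' (b0) measurements; those are used for signal normalization only and are
#' excluded from the forward model and the data-fit energy.
#'
#' @param directions numeric matrix, one unit row vector per measurement.
#' @param bvalues numeric vector of diffusion weightings in s/mm^2.
#' @param b0_threshold b-values at or below this count as b0 (default 10).
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(directions, bvalues, b0_threshold = 10) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3)
    stop("`directions` must have three columns")
  if (nrow(directions) != length(bvalues))
    stop("number of directions and b-values differ")
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  b0 <- bvalues <= b0_threshold
  if (all(b0)) stop("at least one diffusion-weighted (non-b0) entry required")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[!b0] - 1) > 1e-6))
    stop("diffusion-weighted directions must be unit vectors (|norm - 1| <= 1e-6)")
  structure(list(directions = directions, bvalues = as.numeric(bvalues),
                 b0_mask = b0),
            class = "gradient_scheme")
}

#' Tissue model: gray-matter labels and white-matter mask
#'
#' The anatomical prior of the method lives here: fiber endpoints must fall in
#' labeled gray matter (GM) and interior control points in white matter (WM).
#' GM labels are positive integers (0 = not GM); the WM mask is logical.
#' The two compartments must be disjoint. Coordinates are world mm; the affine
#' maps 0-based voxel indices (voxel centers at integer coordinates) to world
#' mm.
#'
#' @param gm_labels 3D integer array of region labels.
#' @param wm_mask 3D logical array, same shape.
#' @param voxel_size length-3 voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform; default diagonal `voxel_size`.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(gm_labels, wm_mask, voxel_size,
                         affine = NULL) {
  gm_labels <- as.array(gm_labels)
  storage.mode(gm_labels) <- "integer"
  wm_mask <- as.array(wm_mask)
  if (!identical(dim(gm_labels), dim(wm_mask)))
    stop("gm_labels and wm_mask must have identical shapes")
  if (length(dim(gm_labels)) != 3) stop("tissue volumes must be 3D")
  if (any(gm_labels < 0)) stop("gm_labels must be >= 0")
  wm_mask <- wm_mask != 0
  if (any(gm_labels > 0 & wm_mask))
    stop("GM and WM voxel sets must be disjoint")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  structure(list(gm_labels = gm_labels, wm_mask = wm_mask,
                 voxel_size = voxel_size, affine = affine),
            class = "tissue_model")
}

#' Diffusion attenuation volume
#'
#' Holds D(x, n) = S(x, n) / S0(x): the diffusion-weighted signal divided
#' voxelwise by the non-weighted signal, one value per gradient-table entry.
#'
#' @param data 4D numeric array (x, y, z, measurement).
#' @param scheme a [gradient_scheme()].
#' @param affine 4x4 voxel-to-world transform.
#' @param mask optional 3D logical array of voxels with valid normalization
#'   (S0 > 0); defaults to all voxels.
#' @return An object of class `attenuation_volume`.
#' @export
attenuation_volume <- function(data, scheme, affine, mask = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 4) stop("attenuation data must be 4D")
  if (dim(data)[4] != nrow(scheme$directions))
    stop("fourth dimension must match the number of scheme directions")
  if (any(!is.finite(data)) || any(data < 0))
    stop("attenuation values must be finite and >= 0")
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3]))
    stop("mask shape must match the spatial grid")
  affine <- as.matrix(affine)
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  structure(list(data = data, scheme = scheme, affine = affine,
                 mask = mask != 0),
            class = "attenuation_volume")
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  storage.mode(points) <- "double"
  points
}

#' Convert between world mm and continuous voxel coordinates
#'
#' Voxel indices are 0-based with voxel centers at integer coordinates.
#'
#' @param points n x 3 matrix (or length-3 vector) of coordinates.
#' @param affine 4x4 voxel-to-world transform.
#' @return n x 3 matrix of transformed coordinates.
#' @export
world_to_voxel <- function(points, affine) {
  points <- as_point_matrix(points)
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(points, affine) {
  points <- as_point_matrix(points)
  h <- cbind(points, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Classify world-mm points against the tissue model
#'
#' Nearest-voxel lookup: a labeled GM voxel wins, then the WM mask, otherwise
#' the point is outside (including points off the grid).
#'
#' @param points n x 3 matrix (or length-3 vector) of world-mm coordinates.
#' @param tissue a [tissue_model()].
#' @return Integer vector: GM label (> 0), `GT_WM`, or `GT_OUTSIDE`.
#' @export
classify_point <- function(points, tissue) {
  points <- as_point_matrix(points)
  v <- world_to_voxel(points, tissue$affine)
  idx <- floor(v + 0.5)
  d <- dim(tissue$gm_labels)
  out <- integer(nrow(points))
  inside <- idx[, 1] >= 0 & idx[, 1] < d[1] &
            idx[, 2] >= 0 & idx[, 2] < d[2] &
            idx[, 3] >= 0 & idx[, 3] < d[3]
  if (any(inside)) {
    lin <- 1 + idx[inside, 1] + d[1] * (idx[inside, 2] + d[2] * idx[inside, 3])
    gm <- tissue$gm_labels[lin]
    wm <- tissue$wm_mask[lin]
    out[inside] <- ifelse(gm > 0L, gm, ifelse(wm, GT_WM, GT_OUTSIDE))
  }
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", nrow(x$directions), "measurements (",
      sum(x$b0_mask), "b0 ),",
      "b =", paste(unique(round(x$bvalues[!x$b0_mask])), collapse = "/"),
      "s/mm^2\n")
  invisible(x)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Tissue model:", paste(dim(x$gm_labels), collapse = " x "),
      "voxels at", paste(x$voxel_size, collapse = " x "), "mm\n")
  cat("  GM: ", sum(x$gm_labels > 0), " voxels in ",
      length(setdiff(unique(as.vector(x$gm_labels)), 0L)), " regions; WM: ",
      sum(x$wm_mask), " voxels\n", sep = "")
  invisible(x)
}

#' @export
print.attenuation_volume <- function(x, ...) {
  cat("Attenuation volume:", paste(dim(x$data), collapse = " x "), "\n")
  print(x$scheme)
  invisible(x)
}
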