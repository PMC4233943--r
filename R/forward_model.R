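# Multi-tensor forward model: per-segment attenuation kernel, whole-volume
# prediction, data-fit energy, NMSE maps, and incrementally updated fiber
# configurations.

#' Forward-model parameters
#'
#' The diffusion tensor of a white-matter segment is axially symmetric with
#' the given eigenvalues (axial first, um^2/ms), rotated so its principal
#' axis follows the segment orientation. Each segment spreads its attenuation
#' over nearby voxels with an isotropic Gaussian kernel of width `sigma`,
#' measured in voxel units; the kernel is truncated at `trunc * sigma`.
#'
#' @param eigenvalues axial + two radial tensor eigenvalues in um^2/ms.
#'   Default `c(2.1, 0.85, 0.85)` (FiberCup acquisition regime).
#' @param sigma Gaussian spread of a segment, in voxel units (default 0.5).
#' @param segment_length spline discretization step in mm (default 2).
#' @param trunc kernel truncation radius in multiples of sigma (default 3;
#'   the truncated amplitude is below 1.3e-4).
#' @return An object of class `forward_params`.
#' @export
forward_params <- function(eigenvalues = c(2.1, 0.85, 0.85), sigma = 0.5,
                           segment_length = 2, trunc = 3) {
  eigenvalues <- as.numeric(eigenvalues)
  if (length(eigenvalues) != 3) stop("three eigenvalues required")
  if (any(eigenvalues < 0) || eigenvalues[1] < max(eigenvalues[2:3]))
    stop("eigenvalues must satisfy axial >= radial >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  if (segment_length <= 0) stop("segment_length must be > 0")
  structure(list(eigenvalues = eigenvalues, sigma = sigma,
                 segment_length = segment_length, trunc = trunc),
            class = "forward_params")
}

# axially symmetric tensor along unit vector nseg; radial = mean of the two
# radial eigenvalues
tensor_adc <- function(n, nseg, eigenvalues) {
  la <- eigenvalues[1]
  lr <- mean(eigenvalues[2:3])
  cosang <- sum(n * nseg)
  lr + (la - lr) * cosang^2
}

#' Attenuation contributed by one segment at one voxel and direction
#'
#' `exp(-b n' D n) * exp(-|x - x_seg|^2 / sigma^2)` with the tensor D
#' oriented along the segment. The spatial distance is measured in voxel
#' units (divide world mm by `voxel_size`), matching the dimensionless
#' kernel width.
#'
#' @param segment list or one-row data.frame with fields/columns
#'   `mx,my,mz` (midpoint, world mm) and `dx,dy,dz` (unit orientation);
#'   a numeric length-6 vector `c(mid, dir)` also works.
#' @param x voxel-center position, world mm.
#' @param n unit gradient direction.
#' @param b b-value in s/mm^2 (0 makes the tensor factor 1).
#' @param eigenvalues tensor eigenvalues, um^2/ms (axial first).
#' @param sigma kernel width in voxel units.
#' @param voxel_size voxel edge in mm used to express the distance in voxel
#'   units (default 1, i.e. distances already in kernel units).
#' @return scalar attenuation.
#' @export
segment_attenuation <- function(segment, x, n, b,
                                eigenvalues = c(2.1, 0.85, 0.85),
                                sigma = 0.5, voxel_size = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.list(segment)) {
    mid <- c(segment$mx, segment$my, segment$mz)
    dir <- c(segment$dx, segment$dy, segment$dz)
  } else {
    mid <- segment[1:3]; dir <- segment[4:6]
  }
  adc <- tensor_adc(n, dir, eigenvalues)           # um^2/ms
  tensor <- exp(-b * 1e-3 * adc)                   # b s/mm^2 * um^2/ms = 1e-3
  d2 <- sum(((x - mid) / voxel_size)^2)
  tensor * exp(-d2 / sigma^2)
}

# shared plumbing: grid geometry of an attenuation volume or tissue model
grid_geometry <- function(x) {
  if (inherits(x, "attenuation_volume"))
    list(dims = dim(x$data)[1:3], affine = x$affine)
  else if (inherits(x, "tissue_model"))
    list(dims = dim(x$gm_labels), affine = x$affine)
  else stop("expected an attenuation_volume or tissue_model")
}

dw_index <- function(scheme) which(!scheme$b0_mask)

#' Predict the diffusion attenuation of a fiber configuration
#'
#' Sums, per voxel and diffusion-weighted direction, the weighted segment
#' attenuations of every fiber (linear in all weights). Segment
#' contributions are truncated beyond `trunc * sigma` voxels from the
#' segment midpoint.
#'
#' @param fibers a [spline_set()].
#' @param grid an [attenuation_volume()] or [tissue_model()] supplying grid
#'   shape and affine.
#' @param scheme a [gradient_scheme()].
#' @param params a [forward_params()].
#' @return 4D array (x, y, z, diffusion-weighted direction). The b0 entries
#'   of the scheme are not represented; the attribute `dw_index` maps the
#'   fourth dimension back to scheme rows.
#' @export
predict_signal <- function(fibers, grid, scheme, params = forward_params()) {
  g <- grid_geometry(grid)
  dw <- dw_index(scheme)
  pred <- cpp_predict_signal(
    fibers$control, fibers$weights, as.integer(g$dims), solve(g$affine),
    scheme$directions[dw, , drop = FALSE], scheme$bvalues[dw],
    params$eigenvalues, params$sigma, params$trunc, params$segment_length)
  pred <- array(pred, c(g$dims, length(dw)))
  attr(pred, "dw_index") <- dw
  pred
}

#' Data-fit energy of a predicted signal
#'
#' Sum of squared differences between prediction and measured attenuation
#' over the masked voxels and the diffusion-weighted (non-b0) directions.
#'
#' @param predicted 4D array from [predict_signal()].
#' @param data an [attenuation_volume()].
#' @param mask 3D logical array of voxels entering the energy; default the
#'   volume's own validity mask.
#' @return scalar energy.
#' @export
energy <- function(predicted, data, mask = NULL) {
  dw <- attr(predicted, "dw_index")
  if (is.null(dw)) dw <- dw_index(data$scheme)
  obs <- data$data[, , , dw, drop = FALSE]
  if (!identical(dim(predicted)[1:4], dim(obs)[1:4]))
    stop("shape mismatch between prediction and data")
  if (is.null(mask)) mask <- data$mask
  if (!identical(dim(mask), dim(data$data)[1:3]))
    stop("mask shape mismatch")
  m4 <- array(mask, dim(obs))
  sum(((predicted - obs)[m4])^2)
}

#' Per-voxel normalized mean-squared error map
#'
#' `NMSE(x) = sum_n (rho(x,n) - D(x,n))^2 / sum_n D(x,n)^2` over the
#' diffusion-weighted directions. Voxels with zero data norm are NA.
#'
#' @inheritParams energy
#' @return 3D array of per-voxel NMSE.
#' @export
nmse_map <- function(predicted, data) {
  dw <- attr(predicted, "dw_index")
  if (is.null(dw)) dw <- dw_index(data$scheme)
  obs <- data$data[, , , dw, drop = FALSE]
  if (!identical(dim(predicted)[1:4], dim(obs)[1:4]))
    stop("shape mismatch between prediction and data")
  num <- apply((predicted - obs)^2, 1:3, sum)
  den <- apply(obs^2, 1:3, sum)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Free-water background prediction
#'
#' Fixed isotropic attenuation `exp(-b * d_iso)` in every voxel outside the
#' white-matter mask, zero inside. Added to the fiber prediction as a known
#' baseline so the energy can be evaluated over the whole image without the
#' background compartment attracting (or being poached by) fibers.
#'
#' @param tissue a [tissue_model()].
#' @param scheme a [gradient_scheme()].
#' @param d_iso free-water diffusivity, um^2/ms (default 2.0).
#' @return 4D array over the diffusion-weighted directions, with attribute
#'   `dw_index`.
#' @export
free_water_baseline <- function(tissue, scheme, d_iso = 2.0) {
  dw <- dw_index(scheme)
  d <- dim(tissue$gm_labels)
  out <- array(0, c(d, length(dw)))
  bg <- !tissue$wm_mask
  for (k in seq_along(dw))
    out[, , , k][bg] <- exp(-scheme$bvalues[dw[k]] * 1e-3 * d_iso)
  attr(out, "dw_index") <- dw
  out
}

# ---------------------------------------------------------------------------
# incrementally updated fiber configuration
# ---------------------------------------------------------------------------

config_contrib <- function(ctrl, cfg) {
  cpp_fiber_contribution(ctrl, cfg$dims, cfg$inv_affine, cfg$dirs, cfg$bvals,
                         cfg$params$eigenvalues, cfg$params$sigma,
                         cfg$params$trunc, cfg$params$segment_length,
                         mask = cfg$mask_int)
}

# apply delta = s * contribution to the cached field and return the energy
# change over the touched entries
config_apply <- function(cfg, contrib, s) {
  if (!length(contrib$voxels)) return(list(cfg = cfg, dE = 0))
  V <- prod(cfg$dims)
  G <- ncol(contrib$values)
  idx <- outer(contrib$voxels + 1L, (seq_len(G) - 1L) * V, `+`)
  before <- cfg$pred[idx]
  after <- before + s * contrib$values
  obs <- cfg$obs[idx]
  cfg$pred[idx] <- after
  dE <- sum((after - obs)^2) - sum((before - obs)^2)
  list(cfg = cfg, dE = dE)
}

#' Fiber configuration with cached prediction and energy
#'
#' Couples a [spline_set()] to a data volume and caches the predicted signal
#' (restricted to the energy mask) and the energy, so that single-fiber
#' changes can be applied incrementally: only voxels within the truncation
#' radius of the affected fiber are touched.
#'
#' @param fibers a [spline_set()].
#' @param data an [attenuation_volume()].
#' @param mask 3D logical energy mask (default the volume's validity mask).
#' @param params a [forward_params()].
#' @param baseline optional fixed background prediction (4D array over the
#'   diffusion-weighted directions, e.g. [free_water_baseline()]).
#' @return An object of class `fiber_configuration` with elements `fibers`,
#'   `pred` (cached field over the mask) and `energy`.
#' @export
fiber_configuration <- function(fibers, data, mask = NULL,
                                params = forward_params(), baseline = NULL) {
  if (is.null(mask)) mask <- data$mask
  g <- grid_geometry(data)
  dw <- dw_index(data$scheme)
  cfg <- list(
    fibers = fibers,
    dims = as.integer(g$dims),
    inv_affine = solve(g$affine),
    dirs = data$scheme$directions[dw, , drop = FALSE],
    bvals = data$scheme$bvalues[dw],
    params = params,
    mask = mask,
    mask_int = as.integer(mask),
    obs = array(data$data[, , , dw, drop = FALSE], c(g$dims, length(dw))),
    contribs = vector("list", length(fibers$control))
  )
  cfg$baseline <- if (is.null(baseline)) array(0, dim(cfg$obs))
                  else array(baseline, dim(cfg$obs))
  cfg$pred <- cfg$baseline
  for (f in seq_along(fibers$control)) {
    cfg$contribs[[f]] <- config_contrib(fibers$control[[f]], cfg)
    cfg <- config_apply(cfg, cfg$contribs[[f]], fibers$weights[f])$cfg
  }
  m4 <- array(mask, dim(cfg$obs))
  cfg$energy <- sum(((cfg$pred - cfg$obs)[m4])^2)
  class(cfg) <- "fiber_configuration"
  cfg
}

#' Incrementally update a fiber configuration
#'
#' Applies a single-fiber change (`weight`, `move`, `add` or `remove`) and
#' updates the cached prediction and energy by touching only the voxels
#' within the truncation radius of the affected fiber's old and new
#' segments.
#'
#' @param config a [fiber_configuration()].
#' @param change one of "weight", "move", "add", "remove".
#' @param fiber index of the affected fiber (ignored for "add").
#' @param weight new weight ("weight"/"add").
#' @param control new control-point matrix ("move"/"add").
#' @return The updated configuration.
#' @export
update_configuration <- function(config, change = c("weight", "move", "add",
                                                    "remove"),
                                 fiber = NULL, weight = NULL, control = NULL) {
  change <- match.arg(change)
  if (change == "weight") {
    w0 <- config$fibers$weights[fiber]
    r <- config_apply(config, config$contribs[[fiber]], weight - w0)
    config <- r$cfg
    config$energy <- config$energy + r$dE
    config$fibers$weights[fiber] <- weight
  } else if (change == "move") {
    w <- config$fibers$weights[fiber]
    r <- config_apply(config, config$contribs[[fiber]], -w)
    config <- r$cfg; dE <- r$dE
    newc <- config_contrib(as_point_matrix(control), config)
    r <- config_apply(config, newc, w)
    config <- r$cfg
    config$energy <- config$energy + dE + r$dE
    config$fibers$control[[fiber]] <- as_point_matrix(control)
    config$contribs[[fiber]] <- newc
  } else if (change == "add") {
    ctrl <- as_point_matrix(control)
    newc <- config_contrib(ctrl, config)
    r <- config_apply(config, newc, weight)
    config <- r$cfg
    config$energy <- config$energy + r$dE
    config$fibers$control <- c(config$fibers$control, list(ctrl))
    config$fibers$weights <- c(config$fibers$weights, weight)
    config$contribs <- c(config$contribs, list(newc))
  } else {
    w <- config$fibers$weights[fiber]
    r <- config_apply(config, config$contribs[[fiber]], -w)
    config <- r$cfg
    config$energy <- config$energy + r$dE
    config$fibers$control[[fiber]] <- NULL
    config$fibers$weights <- config$fibers$weights[-fiber]
    config$contribs[[fiber]] <- NULL
  }
  config
}

#' Audit the cached state of a fiber configuration
#'
#' Recomputes prediction and energy from scratch and compares them with the
#' cache. If the relative energy discrepancy exceeds `tol` the cache is
#' rebuilt and a warning is raised.
#'
#' @param config a [fiber_configuration()].
#' @param tol relative tolerance (default 1e-6).
#' @return list with `energy_cached`, `energy_exact`, `rel_diff`, `config`.
#' @export
audit_configuration <- function(config, tol = 1e-6) {
  pred <- cpp_predict_signal(
    config$fibers$control, config$fibers$weights, config$dims,
    config$inv_affine, config$dirs, config$bvals, config$params$eigenvalues,
    config$params$sigma, config$params$trunc, config$params$segment_length)
  pred <- array(pred, dim(config$obs)) + config$baseline
  m4 <- array(config$mask, dim(config$obs))
  e_exact <- sum(((pred - config$obs)[m4])^2)
  rel <- abs(e_exact - config$energy) / max(1e-12, abs(e_exact))
  if (rel > tol) {
    warning("cache inconsistency detected (rel diff ", signif(rel, 3),
            "); rebuilding")
    config$pred <- pred
    config$energy <- e_exact
  }
  list(energy_cached = config$energy, energy_exact = e_exact,
       rel_diff = rel, config = config)
}
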