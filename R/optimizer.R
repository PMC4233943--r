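# Metropolis-Hastings simulated annealing over fiber weights and geometry
# under hard anatomical constraints. `gtract_fit()` is the main fitting
# entry point and returns a classed object with the usual accessor methods.

#' Simulated-annealing control parameters
#'
#' @param n_iter number of Metropolis iterations (default 2e5). Proposals
#'   rejected for violating the anatomical constraints still count, so the
#'   temperature schedule and runtime stay bounded.
#' @param probs proposal probabilities for change-weight, move, add, remove
#'   (default `c(0.40, 0.40, 0.15, 0.05)`); must sum to 1.
#' @param move_scale standard deviation of the control-point perturbation in
#'   mm; `NULL` means a quarter voxel, set at fit time.
#' @param weight_scale standard deviation of the weight proposal; the new
#'   weight is drawn from a normal centered at the current weight and
#'   truncated to [0, 1] (default 0.05).
#' @param t_start starting temperature; `NULL` auto-calibrates it to the
#'   standard deviation of the energy change over `burn_in` probe proposals.
#' @param t_end_frac final temperature as a fraction of the starting one
#'   (default 1e-3); the decay is geometric.
#' @param burn_in probe proposals for the auto temperature (default 100).
#' @param trace_every record the energy every this many iterations.
#' @param audit_every recompute the energy from scratch every this many
#'   iterations to bound incremental-update drift.
#' @param max_turn_deg hard smoothness constraint: maximum turn angle, in
#'   degrees, between consecutive control-point chords (default 90;
#'   `NULL` disables). Without it the sampler can fold a spline back on
#'   itself inside the white matter, doubling its segment density at half
#'   its weight with no data cost, which destroys the meaning of the
#'   connection strength.
#' @param planar_moves restrict geometry proposals to the axial plane
#'   (default FALSE). For a planar single-slice acquisition the
#'   through-plane position of a fiber is not identifiable from the data
#'   (the spatial kernel does not reach the neighboring slices, so a
#'   through-plane shift only rescales the amplitude, which the weight
#'   absorbs); sampling that direction merely inflates weight variance.
#' @return list of class `sa_control`.
#' @export
sa_control <- function(n_iter = 2e5, probs = c(0.40, 0.40, 0.15, 0.05),
                       move_scale = NULL, weight_scale = 0.05,
                       t_start = NULL, t_end_frac = 1e-3, burn_in = 100,
                       trace_every = 1000, audit_every = 20000,
                       max_turn_deg = 90, planar_moves = FALSE) {
  probs <- as.numeric(probs)
  if (length(probs) != 4 || any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("probs must be 4 non-negative values summing to 1")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(t_start) && t_start <= 0) stop("t_start must be > 0")
  structure(list(n_iter = as.integer(n_iter), probs = probs,
                 move_scale = move_scale, weight_scale = weight_scale,
                 t_start = t_start, t_end_frac = t_end_frac,
                 burn_in = as.integer(burn_in),
                 trace_every = as.integer(trace_every),
                 audit_every = as.integer(audit_every),
                 max_turn_deg = if (is.null(max_turn_deg)) 180
                                else as.numeric(max_turn_deg),
                 planar_moves = isTRUE(planar_moves)),
            class = "sa_control")
}

#' Metropolis acceptance rule
#'
#' A candidate with lower energy is always accepted; otherwise it is
#' accepted when `exp(-dE / T)` exceeds a uniform random number.
#'
#' @param e_current,e_candidate energies of the current and candidate state.
#' @param temperature system temperature (> 0).
#' @param u optional uniform draw in [0, 1) (default `runif(1)`).
#' @return logical.
#' @export
accept <- function(e_current, e_candidate, temperature, u = runif(1)) {
  if (temperature <= 0) stop("temperature must be > 0")
  dE <- e_candidate - e_current
  dE <= 0 || exp(-dE / temperature) > u
}

#' Fit a fiber configuration to diffusion data by simulated annealing
#'
#' Optimizes the weights and control-point geometry of an initial spline
#' library so that the multi-tensor forward prediction best explains the
#' measured attenuation. Four proposals (change a weight, move a fiber,
#' add a fiber, remove a fiber) are drawn with the configured
#' probabilities; candidates whose endpoints leave gray matter or whose
#' interior control points leave white matter are rejected before any
#' energy evaluation, so every visited configuration satisfies the
#' anatomical prior. Removed fibers enter a pool from which the add
#' proposal resurrects them.
#'
#' @param dwi an [attenuation_volume()].
#' @param tissue a [tissue_model()].
#' @param fibers initial [spline_set()]; every fiber must already be
#'   anatomically valid.
#' The energy is evaluated over the whole (valid) image against the sum of
#' the fiber prediction and an optional fixed background `baseline` (such as
#' [free_water_baseline()]); a whole-image data term penalizes fibers that
#' bulge outside the white matter between their control points.
#'
#' @param params a [forward_params()].
#' @param control an [sa_control()].
#' @param seed integer seed; all randomness flows through R's RNG.
#' @param use_best return the best-energy configuration visited (default
#'   TRUE) rather than the last one.
#' @param baseline optional fixed background prediction (4D array over the
#'   diffusion-weighted directions).
#' @return An object of class `gtract_fit` with the optimized fibers,
#'   energies, energy trace and proposal statistics.
#' @export
gtract_fit <- function(dwi, tissue, fibers, params = forward_params(),
                       control = sa_control(), seed = NULL,
                       use_best = TRUE, baseline = NULL) {
  if (!inherits(fibers, "spline_set")) stop("`fibers` must be a spline_set")
  if (!length(fibers$control)) stop("empty initial fiber library")
  ok <- check_anatomical_validity(fibers, tissue)
  if (!all(ok))
    stop(sum(!ok), " initial fiber(s) violate the anatomical constraints")
  if (control$max_turn_deg < 180) {
    turns <- max_chord_turn(fibers)
    if (any(turns > control$max_turn_deg))
      stop(sum(turns > control$max_turn_deg),
           " initial fiber(s) exceed the maximum chord turn angle (",
           control$max_turn_deg, " deg)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(control$move_scale))
    control$move_scale <- 0.25 * min(tissue$voxel_size)

  g <- grid_geometry(dwi)
  dw <- which(!dwi$scheme$b0_mask)
  mask <- dwi$mask
  data_dw <- dwi$data[, , , dw, drop = FALSE]
  base_vec <- if (is.null(baseline)) numeric(0) else as.numeric(baseline)

  res <- cpp_sa_run(
    fibers$control, fibers$weights, as.numeric(data_dw), base_vec,
    as.integer(mask),
    as.integer(tissue$gm_labels), as.integer(tissue$wm_mask),
    as.integer(g$dims), solve(g$affine),
    dwi$scheme$directions[dw, , drop = FALSE], dwi$scheme$bvalues[dw],
    params$eigenvalues, params$sigma, params$trunc, params$segment_length,
    list(n_iter = control$n_iter, probs = control$probs,
         move_scale = control$move_scale,
         weight_scale = control$weight_scale,
         t_start = if (is.null(control$t_start)) NA_real_ else control$t_start,
         t_end_frac = control$t_end_frac, burn_in = control$burn_in,
         trace_every = control$trace_every,
         audit_every = control$audit_every,
         min_chord_cos = if (control$max_turn_deg >= 180) -1
                         else cos(control$max_turn_deg * pi / 180),
         planar_moves = control$planar_moves))

  final <- if (use_best)
    spline_set(res$best_control_points, res$best_weights)
  else
    spline_set(res$control_points, res$weights)

  trace <- as.data.frame(res$trace)
  structure(list(
    fibers = final,
    last_fibers = spline_set(res$control_points, res$weights),
    initial_fibers = fibers,
    energy = if (use_best) res$best_energy else res$energy,
    best_energy = res$best_energy,
    final_energy = res$energy,
    initial_energy = res$initial_energy,
    trace = trace,
    proposal_counts = stats::setNames(res$proposal_counts,
                                      c("weight", "move", "add", "remove")),
    accept_counts = stats::setNames(res$accept_counts,
                                    c("weight", "move", "add", "remove")),
    invalid_proposals = res$invalid_proposals,
    t_start = res$t_start, t_end = res$t_end,
    n_audits = res$n_audits, audit_max_rel = res$audit_max_rel,
    params = params, control = control, seed = seed,
    dwi = dwi, tissue = tissue, baseline = baseline,
    call = match.call()),
    class = "gtract_fit")
}

#' @export
print.gtract_fit <- function(x, ...) {
  cat("Global tractography fit (simulated annealing)\n")
  cat("  fibers: ", length(x$fibers$control), " (initial ",
      length(x$initial_fibers$control), ")\n", sep = "")
  cat(sprintf("  energy: %.4g (initial %.4g, best %.4g)\n",
              x$final_energy, x$initial_energy, x$best_energy))
  cat(sprintf("  iterations: %d; acceptance rate %.1f%%\n",
              x$control$n_iter,
              100 * sum(x$accept_counts) / max(1, sum(x$proposal_counts))))
  invisible(x)
}

#' @export
summary.gtract_fit <- function(object, ...) {
  w <- coef(object)
  pred <- fitted(object)
  if (!is.null(object$baseline)) pred <- pred + object$baseline
  nm <- nmse_map(pred, object$dwi)
  mask <- object$tissue$wm_mask & object$dwi$mask
  out <- list(
    n_fibers = length(object$fibers$control),
    energy = object$energy,
    initial_energy = object$initial_energy,
    energy_reduction = 1 - object$energy / object$initial_energy,
    weights = summary(w),
    mean_wm_nmse = mean(nm[mask], na.rm = TRUE),
    proposal_counts = object$proposal_counts,
    accept_counts = object$accept_counts,
    t_start = object$t_start, t_end = object$t_end)
  class(out) <- "summary.gtract_fit"
  out
}

#' @export
print.summary.gtract_fit <- function(x, ...) {
  cat("Fibers:", x$n_fibers, "\n")
  cat(sprintf("Energy: %.4g (initial %.4g, reduction %.1f%%)\n",
              x$energy, x$initial_energy, 100 * x$energy_reduction))
  cat(sprintf("Mean WM NMSE: %.4f\n", x$mean_wm_nmse))
  cat("Weights:\n"); print(x$weights)
  cat("Proposals drawn:  "); print(x$proposal_counts)
  cat("Proposals accepted:"); print(x$accept_counts)
  invisible(x)
}

#' @export
coef.gtract_fit <- function(object, ...) object$fibers$weights

#' @export
fitted.gtract_fit <- function(object, ...) {
  predict_signal(object$fibers, object$dwi, object$dwi$scheme, object$params)
}

#' @export
residuals.gtract_fit <- function(object, ...) {
  pred <- fitted(object)
  if (!is.null(object$baseline)) pred <- pred + object$baseline
  dw <- attr(pred, "dw_index")
  r <- array(object$dwi$data[, , , dw, drop = FALSE], dim(pred)) - pred
  attr(r, "dw_index") <- dw
  r
}

#' @export
plot.gtract_fit <- function(x, log = "y", ...) {
  tr <- x$trace
  graphics::plot(tr$iteration, tr$energy, type = "l", log = log,
                 xlab = "iteration", ylab = "energy",
                 main = "Annealing energy trace", ...)
  invisible(x)
}

#' Simulate replicate acquisitions from a fitted configuration
#'
#' Draws Rician-noise replicates of the fitted attenuation signal at the
#' given SNR (the measurement model of the synthetic phantom).
#'
#' @param object a [gtract_fit()].
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param snr signal-to-noise ratio (default 20).
#' @param ... unused.
#' @return list of [attenuation_volume()] objects.
#' @export
simulate.gtract_fit <- function(object, nsim = 1, seed = NULL, snr = 20,
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  pred <- fitted(object)
  dw <- attr(pred, "dw_index")
  scheme <- object$dwi$scheme
  sigma <- 1 / snr
  lapply(seq_len(nsim), function(i) {
    atten <- array(0, dim(object$dwi$data))
    atten[, , , scheme$b0_mask] <- 1
    noisy <- sqrt((pred + array(rnorm(length(pred), 0, sigma), dim(pred)))^2 +
                  array(rnorm(length(pred), 0, sigma), dim(pred))^2)
    atten[, , , dw] <- noisy
    attenuation_volume(atten, scheme, object$dwi$affine)
  })
}
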