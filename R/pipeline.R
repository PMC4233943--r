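# End-to-end pipeline: phantom (optional) -> candidate tracking -> library
# preparation -> spline conversion -> weight calibration -> annealing ->
# connectivity evaluation, with artifacts and a provenance log per stage.

#' Default pipeline configuration
#'
#' @param out output directory.
#' @param seed master seed (phantom noise and optimizer).
#' @param snr phantom SNR (ignored when external inputs are given).
#' @param n_iter annealing iterations.
#' @param proposals "all" or "weight-only" (the latter disables the
#'   geometry/add/remove proposals).
#' @param dwi,gm,wm,tracts optional paths to external inputs (NIfTI DWI with
#'   `.bval`/`.bvec` next to it, GM label and WM mask NIfTI, TCK/TRK
#'   candidates). When `dwi` is `NULL` the synthetic phantom is generated.
#' @param threshold,n_points clustering parameters.
#' @param d_iso free-water diffusivity of the fixed background compartment
#'   outside the white matter, um^2/ms (0 disables it).
#' @param weighted_scores score Tractometer percentages by weight.
#' @return list of class `gtract_config`.
#' @export
gtract_config <- function(out = "gtract_out", seed = 1, snr = 20,
                          n_iter = 2e5, proposals = c("all", "weight-only"),
                          dwi = NULL, gm = NULL, wm = NULL, tracts = NULL,
                          threshold = 3, n_points = 25, d_iso = 2.0,
                          weighted_scores = FALSE) {
  proposals <- match.arg(proposals)
  structure(list(out = out, seed = seed, snr = snr, n_iter = n_iter,
                 proposals = proposals, dwi = dwi, gm = gm, wm = wm,
                 tracts = tracts, threshold = threshold, n_points = n_points,
                 d_iso = d_iso, weighted_scores = weighted_scores),
            class = "gtract_config")
}

read_config_file <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(gtract_config, raw)
}

#' Run the full pipeline
#'
#' Executes every stage on the synthetic phantom (default) or on external
#' inputs, writing per-stage artifacts into the output directory: the
#' prepared library and optimized fibers as TCK with a weights sidecar, the
#' energy trace as CSV, an NMSE map as NIfTI, connection matrix and scores
#' as CSV/JSON, and a provenance log. Re-running with the same
#' configuration reproduces the outputs.
#'
#' @param config a [gtract_config()], or a path to a JSON/YAML file with its
#'   fields.
#' @return list with the fitted model, the evaluation and the output paths,
#'   invisibly.
#' @export
run_pipeline <- function(config = gtract_config()) {
  if (is.character(config)) config <- read_config_file(config)
  stopifnot(inherits(config, "gtract_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out, "provenance.json")
  t0 <- Sys.time()

  if (is.null(config$dwi)) {
    message("[phantom] generating synthetic dataset (SNR ", config$snr, ")")
    phantom <- generate_phantom(phantom_spec(snr = config$snr,
                                             seed = config$seed))
    tissue <- phantom$tissue
    dwi <- phantom$dwi
    truth <- phantom$truth
    write_phantom(phantom, file.path(config$out, "phantom"))
  } else {
    dwi <- read_dwi(config$dwi, sub("\\.nii(\\.gz)?$", ".bval", config$dwi),
                    sub("\\.nii(\\.gz)?$", ".bvec", config$dwi))
    gmv <- read_nifti_vol(config$gm)
    wmv <- read_nifti_vol(config$wm)
    vs <- sqrt(colSums(gmv$affine[1:3, 1:3]^2))
    tissue <- tissue_model(gmv$data, wmv$data != 0, vs, gmv$affine)
    truth <- NULL
  }

  if (is.null(config$tracts)) {
    message("[track] running the built-in deterministic tracker")
    cand <- track_candidates(dwi, tissue)
  } else {
    cand <- read_tractogram(config$tracts)
  }
  message("[track] ", length(cand$streamlines), " candidate streamlines")

  params <- forward_params()
  message("[prep] filtering, clustering, spline conversion, calibration")
  fibers <- prepare_library(cand, dwi, tissue, params,
                            threshold = config$threshold,
                            n_points = config$n_points,
                            d_iso = config$d_iso)
  message("[prep] ", length(fibers$control), " fibers at initial weight ",
          signif(fibers$weights[1], 4))
  write_spline_set(fibers, file.path(config$out, "initial_library.tck"))

  probs <- if (config$proposals == "weight-only") c(1, 0, 0, 0)
           else c(0.40, 0.40, 0.15, 0.05)
  message("[optimize] ", config$n_iter, " iterations (", config$proposals,
          " proposals), seed ", config$seed)
  baseline <- if (config$d_iso > 0)
    free_water_baseline(tissue, dwi$scheme, config$d_iso) else NULL
  fit <- gtract_fit(dwi, tissue, fibers, params,
                    control = sa_control(n_iter = config$n_iter,
                                         probs = probs,
                                         planar_moves = is.null(config$dwi)),
                    seed = config$seed, baseline = baseline)
  message(sprintf("[optimize] energy %.4g -> %.4g", fit$initial_energy,
                  fit$best_energy))
  write_spline_set(fit$fibers, file.path(config$out, "optimized.tck"))
  write.csv(fit$trace, file.path(config$out, "energy_trace.csv"),
            row.names = FALSE)
  pred <- fitted(fit)
  if (!is.null(baseline)) pred <- pred + baseline
  write_nifti_vol(replace_na(nmse_map(pred, dwi), -1),
                  dwi$affine, file.path(config$out, "nmse.nii.gz"))

  result <- list(fit = fit, out = config$out)
  if (!is.null(truth)) {
    ev <- evaluate_connectivity(fit$fibers, tissue, truth,
                                weighted = config$weighted_scores)
    write.csv(unclass(ev$matrix),
              file.path(config$out, "connection_matrix.csv"))
    scores <- list(
      raw = unclass(ev$scores_raw)[c("vc", "ic", "nc", "vb", "ib")],
      classified = unclass(ev$scores_classified)[c("vc", "ic", "nc", "vb",
                                                   "ib")])
    jsonlite::write_json(scores, file.path(config$out, "scores.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf(
      "[evaluate] VC %.1f%%  IC %.1f%%  NC %.1f%%  VB %d  IB %d (classified)",
      ev$scores_classified$vc, ev$scores_classified$ic,
      ev$scores_classified$nc, ev$scores_classified$vb,
      ev$scores_classified$ib))
    result$evaluation <- ev
  }

  cfg_file <- file.path(config$out, "config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_file)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("gtract")),
               r_version = R.version.string,
               elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")))
  jsonlite::write_json(prov, log_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}

replace_na <- function(x, value) { x[is.na(x)] <- value; x }

#' Export a spline set as TCK plus JSON control points
#'
#' Writes the fibers densely sampled (0.5 mm) as TCK with a weights
#' sidecar, and the exact control points and weights as JSON next to it.
#'
#' @param fibers a [spline_set()].
#' @param path output TCK path.
#' @param step sampling step in mm.
#' @return `path`, invisibly.
#' @export
write_spline_set <- function(fibers, path, step = 0.5) {
  polys <- sample_splines(fibers, step)
  write_tractogram(tractogram(polys, weights = fibers$weights), path)
  jsonlite::write_json(
    list(control_points = fibers$control, weights = fibers$weights),
    sub("\\.tck$", ".json", path), digits = NA)
  invisible(path)
}

#' Read a spline set written by [write_spline_set()]
#'
#' @param json_path the JSON sidecar path.
#' @return A [spline_set()].
#' @export
read_spline_set <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  ctrl <- if (is.list(obj$control_points)) lapply(obj$control_points, as.matrix)
          else apply(obj$control_points, 1, identity, simplify = FALSE)
  spline_set(ctrl, obj$weights)
}
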