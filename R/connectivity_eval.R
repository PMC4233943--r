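# Connectivity evaluation: connection-strength matrices, two-means
# valid/invalid bundle classification, Tractometer-style scores, and
# reproducibility (coefficient of variation over runs).

fiber_endpoint_labels <- function(fibers, tissue) {
  t(vapply(fibers$control, function(C) {
    cls <- classify_point(C[c(1, nrow(C)), , drop = FALSE], tissue)
    as.integer(cls)
  }, integer(2)))
}

#' Connection-strength matrix
#'
#' Symmetric region-by-region matrix whose (i, j) entry is the sum of the
#' weights of all fibers with one endpoint in region i and the other in
#' region j. Fibers with any endpoint outside gray matter are excluded.
#'
#' @param fibers a [spline_set()].
#' @param tissue a [tissue_model()].
#' @param n_rois number of regions (default: the largest GM label).
#' @return n_rois x n_rois numeric matrix of class `connection_matrix`.
#' @export
connection_matrix <- function(fibers, tissue, n_rois = NULL) {
  if (is.null(n_rois)) n_rois <- max(tissue$gm_labels)
  M <- matrix(0, n_rois, n_rois,
              dimnames = list(seq_len(n_rois), seq_len(n_rois)))
  if (length(fibers$control)) {
    ends <- fiber_endpoint_labels(fibers, tissue)
    for (f in seq_len(nrow(ends))) {
      a <- ends[f, 1]; b <- ends[f, 2]
      if (a > 0 && b > 0) {
        M[a, b] <- M[a, b] + fibers$weights[f]
        if (a != b) M[b, a] <- M[b, a] + fibers$weights[f]
      }
    }
  }
  if (any(diag(M) > 0)) attr(M, "self_connections") <- which(diag(M) > 0)
  class(M) <- c("connection_matrix", class(M))
  M
}

#' Classify bundle strengths as valid or invalid
#'
#' One-dimensional 2-means on the connection strengths; the cluster with
#' the larger centroid is called valid. In one dimension the optimal
#' 2-means clusters are intervals, so the global optimum is found exactly
#' by scanning every split of the sorted strengths for the minimum
#' within-cluster sum of squares (iterative refinement from a fixed
#' initialization can stall in a local optimum). With all strengths equal a
#' single effective cluster remains and everything is called valid (with a
#' warning).
#'
#' @param strengths named or unnamed numeric vector of (nonzero) bundle
#'   strengths.
#' @return Character vector (`"valid"`/`"invalid"`) aligned with
#'   `strengths`, with centroids attached as attribute `centers`.
#' @export
classify_bundles <- function(strengths) {
  x <- as.numeric(strengths)
  if (!length(x)) stop("no bundle strengths to classify")
  if (length(x) == 1 || diff(range(x)) == 0) {
    if (diff(range(x)) == 0 && length(x) > 1)
      warning("all strengths equal: single effective cluster, all valid")
    out <- rep("valid", length(x))
    names(out) <- names(strengths)
    return(structure(out, centers = mean(x)))
  }
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf; split <- 1L
  for (s in seq_len(n - 1)) {
    val <- sse(xs[1:s]) + sse(xs[(s + 1):n])
    if (val < best) { best <- val; split <- s }
  }
  cl <- integer(n)
  cl[ord] <- rep(1:2, c(split, n - split))
  centers <- c(mean(xs[1:split]), mean(xs[(split + 1):n]))
  out <- ifelse(cl == 2, "valid", "invalid")
  names(out) <- names(strengths)
  structure(out, centers = centers)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

#' Tractometer-style connectivity scores
#'
#' Classifies every fiber against the ground-truth bundle list: VC (valid
#' connection: endpoint region pair is a true bundle), IC (invalid: both
#' endpoints in regions, but the pair is not a true bundle), NC
#' (non-connecting: fewer than two endpoints in gray-matter regions).
#' VC/IC/NC are percentages of the per-fiber contribution (count by
#' default, weight if `weighted`); VB and IB are absolute bundle counts.
#'
#' @param fibers a [spline_set()].
#' @param tissue a [tissue_model()].
#' @param truth a ground-truth object with a `pairs` matrix (from
#'   [build_phantom()]), or a 2-column matrix of true region pairs.
#' @param weighted use fiber weights instead of counts (default FALSE).
#' @return list of class `tractometer_scores`: `vc`, `ic`, `nc` (percent),
#'   `vb`, `ib` (counts), plus the per-fiber `category`.
#' @export
tractometer_scores <- function(fibers, tissue, truth, weighted = FALSE) {
  pairs <- if (is.matrix(truth)) truth else truth$pairs
  gt_keys <- unique(pair_key(pairs[, 1], pairs[, 2]))
  n <- length(fibers$control)
  category <- character(n)
  keys <- character(n)
  if (n) {
    ends <- fiber_endpoint_labels(fibers, tissue)
    for (f in seq_len(n)) {
      a <- ends[f, 1]; b <- ends[f, 2]
      if (a <= 0 || b <= 0) {
        category[f] <- "NC"
      } else {
        keys[f] <- pair_key(a, b)
        category[f] <- if (keys[f] %in% gt_keys) "VC" else "IC"
      }
    }
  }
  contrib <- if (weighted) fibers$weights else rep(1, n)
  total <- sum(contrib)
  pct <- function(cat) if (total > 0) 100 * sum(contrib[category == cat]) / total else 0
  vb <- length(unique(keys[category == "VC"]))
  ib <- length(unique(keys[category == "IC"]))
  structure(list(vc = pct("VC"), ic = pct("IC"), nc = pct("NC"),
                 vb = vb, ib = ib, category = category),
            class = "tractometer_scores")
}

#' @export
print.tractometer_scores <- function(x, ...) {
  cat(sprintf("VC %.2f%%  IC %.2f%%  NC %.2f%%  VB %d  IB %d\n",
              x$vc, x$ic, x$nc, x$vb, x$ib))
  invisible(x)
}

#' Reproducibility: mean coefficient of variation of connection strengths
#'
#' Per-cell CV (sample standard deviation over mean, across runs) of the
#' connection-strength matrices, averaged over the cells whose mean is
#' nonzero. Only the upper triangle (including the diagonal) is used.
#'
#' @param matrices list of equally shaped [connection_matrix()] objects.
#' @return Mean CV (dimensionless; multiply by 100 for percent).
#' @export
reproducibility_cv <- function(matrices) {
  if (length(matrices) < 2) stop("need at least 2 matrices")
  d <- dim(matrices[[1]])
  if (!all(vapply(matrices, function(m) identical(dim(m), d), TRUE)))
    stop("matrices must have identical shapes")
  ut <- upper.tri(matrices[[1]], diag = TRUE)
  cells <- sapply(matrices, function(m) m[ut])   # n_cells x n_runs
  mu <- rowMeans(cells)
  keep <- mu != 0
  if (!any(keep)) return(NA_real_)
  cv <- apply(cells[keep, , drop = FALSE], 1, sd) / mu[keep]
  mean(cv)
}

#' Classify bundles and score the retained fibers
#'
#' The post-optimization evaluation: builds the connection matrix, runs the
#' two-means strength classification on the nonzero bundles, retains the
#' fibers belonging to valid-classified bundles, and computes
#' Tractometer-style scores on both the raw and the retained fiber sets.
#'
#' The classification runs over every region pair of the matrix (including
#' zero-strength pairs, as in a full connectivity-matrix display): absent
#' connections anchor the low-strength cluster, so a candidate set without
#' spurious bundles does not get its weakest true bundles discarded.
#'
#' @param fibers a [spline_set()].
#' @param tissue a [tissue_model()].
#' @param truth ground truth (see [tractometer_scores()]).
#' @param weighted score by weight instead of count (default FALSE).
#' @return list with `matrix`, `classification` (nonzero pairs only),
#'   `retained` (a [spline_set()]), `scores_raw`, `scores_classified`.
#' @export
evaluate_connectivity <- function(fibers, tissue, truth, weighted = FALSE) {
  M <- connection_matrix(fibers, tissue)
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  strengths <- M[ut]
  names(strengths) <- pair_key(ut[, 1], ut[, 2])
  cls_all <- classify_bundles(strengths)
  cls <- cls_all[strengths > 0]
  valid_keys <- names(cls)[cls == "valid"]
  ends <- fiber_endpoint_labels(fibers, tissue)
  fiber_keys <- pair_key(ends[, 1], ends[, 2])
  keep <- ends[, 1] > 0 & ends[, 2] > 0 & fiber_keys %in% valid_keys
  retained <- spline_set(fibers$control[keep], fibers$weights[keep])
  list(matrix = M, classification = cls, retained = retained,
       scores_raw = tractometer_scores(fibers, tissue, truth, weighted),
       scores_classified = tractometer_scores(retained, tissue, truth,
                                              weighted))
}
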