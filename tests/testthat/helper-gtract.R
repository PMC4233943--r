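# Shared fixtures and independent reference implementations ("oracles")
# used across the test files. The oracles deliberately avoid the package's
# compiled code paths: attenuations via explicit rotation matrices, signal
# prediction via untruncated triple loops, energies via naive summation.

# --- fixtures ---------------------------------------------------------------

# minimal tissue model: a straight horizontal WM tube in the middle slice of
# a small slab, GM discs at both ends
straight_tissue <- function(nx = 16, ny = 9, nz = 3, vs = 3) {
  gm <- array(0L, c(nx, ny, nz))
  wm <- array(FALSE, c(nx, ny, nz))
  zm <- floor(nz / 2) + 1
  yc <- floor(ny / 2) + 1
  gm[2, yc + (-1:1), zm] <- 1L
  gm[3, yc, zm] <- 1L
  gm[nx - 1, yc + (-1:1), zm] <- 2L
  gm[nx - 2, yc, zm] <- 2L
  wm[4:(nx - 3), yc + (-1:1), zm] <- TRUE
  tissue_model(gm, wm, rep(vs, 3))
}

# single straight bundle phantom in a small grid (fast)
straight_phantom_spec <- function(snr = Inf, weight = 0.3, d_iso = 0,
                                  seed = 1, nx = 24, ny = 13) {
  vs <- 3
  y0 <- (floor(ny / 2)) * vs
  bundle <- list(rois = c(1L, 2L),
                 points = cbind(seq(2 * vs, (nx - 3) * vs, length.out = 100),
                                y0))
  phantom_spec(dims = c(nx, ny, 3), voxel_size = vs, bundles = list(bundle),
               snr = snr, weight = weight, d_iso = d_iso, seed = seed)
}

# small shared default phantom (cached per test run)
cached_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- generate_phantom(phantom_spec(snr = 20, seed = 1))
    ph
  }
})

# --- oracles ----------------------------------------------------------------

# attenuation of one segment via an explicit rotation matrix R'ated tensor
oracle_segment_attenuation <- function(mid, nseg, x, n, b, eigenvalues,
                                       sigma, voxel_size = 1) {
  # orthonormal frame with first axis along the segment
  e1 <- nseg / sqrt(sum(nseg^2))
  a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3)
  lam <- c(eigenvalues[1], mean(eigenvalues[2:3]), mean(eigenvalues[2:3]))
  D <- R %*% diag(lam) %*% t(R)
  adc <- as.numeric(t(n) %*% D %*% n)
  d2 <- sum(((x - mid) / voxel_size)^2)
  exp(-b * 1e-3 * adc) * exp(-d2 / sigma^2)
}

# untruncated brute-force prediction over the whole grid (R triple loop)
oracle_predict <- function(fibers, dims, affine, scheme, params) {
  dw <- which(!scheme$b0_mask)
  out <- array(0, c(dims, length(dw)))
  vs <- sqrt(sum(affine[1:3, 1]^2))   # isotropic grids only
  centers <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                   z = 0:(dims[3] - 1)))
  world <- voxel_to_world(centers, affine)
  for (f in seq_along(fibers$control)) {
    segs <- discretize(fibers$control[[f]], params$segment_length)
    w <- fibers$weights[f]
    for (s in seq_len(nrow(segs))) {
      mid <- c(segs$mx[s], segs$my[s], segs$mz[s])
      nseg <- c(segs$dx[s], segs$dy[s], segs$dz[s])
      for (v in seq_len(nrow(world))) {
        for (k in seq_along(dw)) {
          g <- dw[k]
          out[centers[v, 1] + 1, centers[v, 2] + 1, centers[v, 3] + 1, k] <-
            out[centers[v, 1] + 1, centers[v, 2] + 1, centers[v, 3] + 1, k] +
            w * oracle_segment_attenuation(mid, nseg, world[v, ],
                                           scheme$directions[g, ],
                                           scheme$bvalues[g],
                                           params$eigenvalues, params$sigma,
                                           voxel_size = vs)
        }
      }
    }
  }
  attr(out, "dw_index") <- dw
  out
}

# naive two-loop energy
oracle_energy <- function(predicted, data, mask) {
  dw <- attr(predicted, "dw_index")
  total <- 0
  d <- dim(predicted)
  for (k in seq_len(d[4])) {
    for (v in which(mask)) {
      idx <- arrayInd(v, d[1:3])
      total <- total + (predicted[idx[1], idx[2], idx[3], k] -
                        data$data[idx[1], idx[2], idx[3], dw[k]])^2
    }
  }
  total
}

# exhaustive 1-D two-cluster assignment minimizing within-cluster SSE:
# enumerates every non-trivial bipartition (no interval assumption)
oracle_two_means <- function(x) {
  n <- length(x)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  best <- Inf; best_in_hi <- NULL
  for (code in 1:(2^n - 2)) {
    hi <- as.logical(bitwAnd(code, 2^(0:(n - 1))) > 0)
    val <- sse(x[hi]) + sse(x[!hi])
    if (val < best) { best <- val; best_in_hi <- hi }
  }
  if (mean(x[best_in_hi]) < mean(x[!best_in_hi])) best_in_hi <- !best_in_hi
  ifelse(best_in_hi, "valid", "invalid")
}

# dense-quadrature arc length of a Catmull-Rom spline
oracle_arc_length <- function(ctrl, n = 20000) {
  pts <- catmull_rom_evaluate(ctrl, seq(0, 1, length.out = n))
  sum(sqrt(rowSums(diff(pts)^2)))
}
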