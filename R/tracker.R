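# Deterministic streamline tracker for candidate generation on the planar
# phantom. Local fiber orientations are estimated per voxel by
# Richardson-Lucy deconvolution of the measured attenuation profile with
# the package's own single-tensor response, on a circle of in-plane
# orientations; streamlines follow the deconvolved peaks. This resolves
# crossings, where raw minimum-attenuation tracking bends toward the
# bisector. It is a self-contained candidate generator, not a faithful
# re-implementation of any published tracker.

# per-voxel orientation distributions: rows = voxels, cols = K axial
# orientation bins over [0, 180) degrees in the axial plane
rl_odf <- function(Y, dirs3d, bvals, eigenvalues, K = 90, n_iter = 60) {
  theta <- (seq_len(K) - 0.5) * pi / K
  u <- cbind(cos(theta), sin(theta), 0)
  la <- eigenvalues[1]; lr <- mean(eigenvalues[2:3])
  cosang <- dirs3d %*% t(u)                     # G x K
  D <- exp(-(bvals * 1e-3) * (lr + (la - lr) * cosang^2))
  Ft <- matrix(1, nrow(Y), K)
  cs <- colSums(D)
  for (i in seq_len(n_iter)) {
    P <- Ft %*% t(D)
    ratio <- Y / pmax(P, 1e-12)
    Ft <- Ft * (ratio %*% D) / rep(cs, each = nrow(Ft))
  }
  list(odf = Ft, theta = theta)
}

# circular (period K) peak extraction: local maxima over +/- w bins that
# reach at least `rel` of the voxel's maximum; at most n_max peaks
odf_peaks <- function(odf, w = 7, rel = 0.5, n_max = 3) {
  K <- ncol(odf)
  apply(odf, 1, function(f) {
    mx <- max(f)
    if (mx <= 0) return(integer(0))
    is_peak <- vapply(seq_len(K), function(k) {
      nb <- ((k - 1 + c(-(w:1), 1:w)) %% K) + 1
      f[k] >= max(f[nb]) && f[k] >= rel * mx
    }, logical(1))
    p <- which(is_peak)
    if (length(p) > n_max) p <- p[order(f[p], decreasing = TRUE)[1:n_max]]
    p
  }, simplify = FALSE)
}

#' Deterministic peak-following streamline tracker
#'
#' Seeds streamlines from every white-matter voxel and propagates them in
#' both directions along the local fiber orientations, which are estimated
#' once per voxel by Richardson-Lucy deconvolution of the attenuation
#' profile with the forward model's tensor response (in-plane orientations;
#' the phantom slab is planar). At each step the peak closest to the
#' incoming direction is followed; tracking stops when the streamline
#' leaves the tissue model, enters gray matter, or no peak lies within
#' `max_angle` of the previous step.
#'
#' @param dwi an [attenuation_volume()].
#' @param tissue a [tissue_model()].
#' @param params a [forward_params()] (tensor response of the deconvolution).
#' @param step_mm step size in mm (default half a voxel).
#' @param max_angle curvature gate per step, degrees (default 45).
#' @param max_steps per-direction step limit (default 500).
#' @param min_points minimum points for a streamline to be kept (default 4).
#' @param n_orient orientation bins over 180 degrees (default 90).
#' @param peak_rel relative height threshold for secondary peaks.
#' @param smooth spatially average the attenuation over the in-plane
#'   4-neighborhood before deconvolution (default TRUE; stabilizes the
#'   orientation estimates under noise).
#' @param coast_steps number of consecutive steps the tracker may continue
#'   straight through a voxel whose orientation distribution offers no
#'   peak within the gate (default 2); bridges isolated noisy voxels.
#' @param dilate in-plane dilation (voxels) of the white-matter mask
#'   defining the tracking domain (default 1). The spatial kernel spreads a
#'   bundle's signal beyond its nominal mask, so the adjacent
#'   partial-volume shell still carries usable orientation information; a
#'   strict mask truncates slightly drifting walkers mid-bundle.
#' @return A [tractogram()].
#' @export
track_candidates <- function(dwi, tissue, params = forward_params(),
                             step_mm = min(tissue$voxel_size) / 2,
                             max_angle = 45, max_steps = 500, min_points = 4,
                             n_orient = 90, peak_rel = 0.5, smooth = TRUE,
                             coast_steps = 2, dilate = 1) {
  d <- dim(tissue$gm_labels)
  dw <- which(!dwi$scheme$b0_mask)
  dirs3d <- dwi$scheme$directions[dw, , drop = FALSE]
  A <- dwi$data[, , , dw, drop = FALSE]
  if (smooth) {
    sh <- function(a, off) {
      idx <- pmin(pmax(seq_len(d[1]) + off[1], 1), d[1])
      idy <- pmin(pmax(seq_len(d[2]) + off[2], 1), d[2])
      a[idx, idy, , , drop = FALSE]
    }
    A <- (A + sh(A, c(1, 0)) + sh(A, c(-1, 0)) + sh(A, c(0, 1)) +
          sh(A, c(0, -1))) / 5
  }
  V <- prod(d)
  Am <- matrix(A, V, length(dw))

  shift_mask <- function(m, off) {
    idx <- pmin(pmax(seq_len(d[1]) + off[1], 1), d[1])
    idy <- pmin(pmax(seq_len(d[2]) + off[2], 1), d[2])
    m[idx, idy, , drop = FALSE]
  }
  dilate_mask <- function(m, n) {
    for (i in seq_len(n))
      m <- m | shift_mask(m, c(1, 0)) | shift_mask(m, c(-1, 0)) |
           shift_mask(m, c(0, 1)) | shift_mask(m, c(0, -1))
    m
  }
  wm_lin <- which(as.vector(tissue$wm_mask))
  domain <- tissue$wm_mask
  if (dilate > 0) {
    gm_mask <- tissue$gm_labels > 0
    # partial-volume shell around the WM; voxels adjacent to gray matter
    # are excluded from the shell (but not from the WM itself) so that a
    # drifting walker cannot slide around a region instead of entering it
    shell <- dilate_mask(tissue$wm_mask, dilate) & !tissue$wm_mask &
             !dilate_mask(gm_mask, 1)
    domain <- domain | shell
  }

  dom_lin <- which(as.vector(domain))
  odf <- rl_odf(Am[dom_lin, , drop = FALSE], dirs3d, dwi$scheme$bvalues[dw],
                params$eigenvalues, K = n_orient)
  peaks <- odf_peaks(odf$odf, w = max(2, round(n_orient / 12)),
                     rel = peak_rel)
  theta <- odf$theta
  peak_of <- vector("list", V)
  peak_of[dom_lin] <- peaks
  in_domain <- as.vector(domain)

  cosgate <- cos(max_angle * pi / 180)
  inv <- solve(tissue$affine)
  vox_of <- function(p) {
    v <- floor((inv %*% c(p, 1))[1:3] + 0.5)
    if (any(v < 0) || any(v >= d)) return(NA_integer_)
    as.integer(1 + v[1] + d[1] * (v[2] + d[2] * v[3]))
  }
  dir_of <- function(th) c(cos(th), sin(th), 0)

  # peak orientation closest to the previous direction, or NULL
  next_dir <- function(lin, prev) {
    p <- peak_of[[lin]]
    if (is.null(p) || !length(p)) return(NULL)
    best <- NULL; best_c <- cosgate
    for (k in p) {
      u <- dir_of(theta[k])
      ca <- sum(u * prev)
      if (abs(ca) >= best_c) { best_c <- abs(ca); best <- u * sign(ca) }
    }
    best
  }

  propagate <- function(p0, d0) {
    pts <- list(p0)
    p <- p0; dr <- d0
    coast <- 0
    for (k in seq_len(max_steps)) {
      p_new <- p + step_mm * dr
      lin <- vox_of(p_new)
      if (is.na(lin)) break
      cls <- classify_point(p_new, tissue)
      if (cls == GT_OUTSIDE && !in_domain[lin]) break
      pts[[length(pts) + 1]] <- p_new
      if (cls > 0) break                 # reached gray matter
      nd <- next_dir(lin, dr)
      if (is.null(nd)) {
        coast <- coast + 1               # keep direction through a bad voxel
        if (coast > coast_steps) break
        p <- p_new
      } else {
        coast <- 0
        p <- p_new; dr <- nd
      }
    }
    do.call(rbind, pts)
  }

  seeds <- arrayInd(wm_lin, d) - 1L
  streamlines <- list()
  for (i in seq_along(wm_lin)) {
    pk <- peak_of[[wm_lin[i]]]
    if (!length(pk)) next
    p0 <- (tissue$affine %*% c(seeds[i, ], 1))[1:3]
    for (k in pk) {
      d0 <- dir_of(theta[k])
      fwd <- propagate(p0, d0)
      bwd <- propagate(p0, -d0)
      s <- rbind(bwd[nrow(bwd):1, , drop = FALSE], fwd[-1, , drop = FALSE])
      if (nrow(s) >= min_points) {
        keep <- c(TRUE, rowSums(diff(s)^2) > 0)
        streamlines[[length(streamlines) + 1]] <- s[keep, , drop = FALSE]
      }
    }
  }
  tractogram(streamlines, affine = tissue$affine)
}
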