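test_that("default phantom has 7 bundles, 12 regions, disjoint tissue", {
  ph <- build_phantom(phantom_spec())
  expect_equal(nrow(ph$truth$pairs), 7)
  labels <- setdiff(unique(as.vector(ph$tissue$gm_labels)), 0L)
  expect_length(labels, 12)
  expect_false(any(ph$tissue$gm_labels > 0 & ph$tissue$wm_mask))
  # pairs unique, each connecting distinct regions
  keys <- apply(ph$truth$pairs, 1, function(p) paste(sort(p), collapse = "-"))
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(ph$truth$pairs[, 1] != ph$truth$pairs[, 2]))
  # the ground-truth splines themselves satisfy the anatomical prior
  expect_true(all(check_anatomical_validity(
    spline_set(ph$truth$splines), ph$tissue)))
})

test_that("a straight single-bundle spec paints a straight tube into GM", {
  spec <- straight_phantom_spec()
  ph <- build_phantom(spec)
  wm_idx <- which(ph$tissue$wm_mask, arr.ind = TRUE)
  # a straight tube: all WM in the middle slice, y within the tube radius
  yc <- floor(dim(ph$tissue$gm_labels)[2] / 2)
  expect_true(all(abs(wm_idx[, 2] - 1 - yc) * 3 <= spec$tube_radius))
  expect_true(all(wm_idx[, 3] == 2))
  ends <- classify_point(rbind(ph$truth$centerlines[[1]][1, ],
                               ph$truth$centerlines[[1]][100, ]), ph$tissue)
  expect_equal(sort(ends), c(1L, 2L))
  # overlapping region labels raise an error
  bad <- straight_phantom_spec()
  bad$bundles[[2]] <- list(rois = c(3L, 4L),
                           points = bad$bundles[[1]]$points + 1)
  expect_error(build_phantom(bad), "overlapping")
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(phantom_spec(snr = 15, seed = 99))
  b <- generate_phantom(phantom_spec(snr = 15, seed = 99))
  expect_identical(a$dwi$data, b$dwi$data)
  expect_identical(a$tissue$gm_labels, b$tissue$gm_labels)
  c <- generate_phantom(phantom_spec(snr = 15, seed = 100))
  expect_false(identical(a$dwi$data, c$dwi$data))
})

test_that("noiseless attenuation along a straight tube matches closed form", {
  spec <- straight_phantom_spec(snr = Inf, weight = 0.3)
  ph <- generate_phantom(spec)
  scheme <- ph$scheme
  # mid-tube voxel far from both ends
  d <- dim(ph$tissue$gm_labels)
  yc <- floor(d[2] / 2); xm <- floor(d[1] / 2)
  vs <- 3
  x_world <- c(xm, yc, 1) * vs
  # oracle: sum closed-form per-segment attenuations over the fiber
  segs <- discretize(ph$truth$splines[[1]], 2)
  for (g in c(2, 20, 40)) {
    n <- scheme$directions[g, ]
    b <- scheme$bvalues[g]
    want <- 0.3 * sum(vapply(seq_len(nrow(segs)), function(s)
      oracle_segment_attenuation(c(segs$mx[s], segs$my[s], segs$mz[s]),
                                 c(segs$dx[s], segs$dy[s], segs$dz[s]),
                                 x_world, n, b, c(2.1, 0.85, 0.85), 0.5,
                                 voxel_size = 3), 0))
    got <- ph$dwi$data[xm + 1, yc + 1, 2, g]
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("infinite SNR equals noiseless and noise vanishes as SNR grows", {
  spec0 <- straight_phantom_spec(snr = Inf)
  ph0 <- generate_phantom(spec0)
  spec_hi <- straight_phantom_spec(snr = 1e7)
  ph_hi <- generate_phantom(spec_hi)
  expect_lt(max(abs(ph_hi$dwi$data[, , , -1] - ph0$dwi$data[, , , -1])),
            1e-6)
})

test_that("disjoint bundles contribute independently to the signal", {
  vs <- 3
  b1 <- list(rois = c(1L, 2L),
             points = cbind(seq(6, 57, length.out = 80), 9))
  b2 <- list(rois = c(3L, 4L),
             points = cbind(seq(6, 57, length.out = 80), 45))
  spec <- phantom_spec(dims = c(22, 19, 3), voxel_size = vs,
                       bundles = list(b1, b2), snr = Inf, d_iso = 0)
  ph <- build_phantom(spec)
  scheme <- phantom_scheme(16, 1500)
  full <- simulate_dwi(ph$truth, ph$tissue, scheme, snr = Inf, d_iso = 0)
  solo <- ph$truth
  solo$weights <- c(spec$weight, 0)
  one <- simulate_dwi(solo, ph$tissue, scheme, snr = Inf, d_iso = 0)
  # voxels near bundle 1 are unaffected by bundle 2's weight
  near1 <- which(ph$tissue$wm_mask, arr.ind = TRUE)
  near1 <- near1[near1[, 2] <= 7, , drop = FALSE]
  for (r in seq_len(min(10, nrow(near1))))
    expect_equal(full$data[near1[r, 1], near1[r, 2], near1[r, 3], ],
                 one$data[near1[r, 1], near1[r, 2], near1[r, 3], ],
                 tolerance = 1e-12)
})

test_that("true configuration has zero energy on its own noiseless data", {
  spec <- phantom_spec(snr = Inf, seed = 1)
  ph <- build_phantom(spec)
  scheme <- phantom_scheme(spec$n_dirs, spec$bvalue)
  dwi <- simulate_dwi(ph$truth, ph$tissue, scheme, snr = Inf,
                      d_iso = spec$d_iso)
  pred <- predict_signal(spline_set(ph$truth$splines, ph$truth$weights),
                         ph$tissue, scheme) +
          free_water_baseline(ph$tissue, scheme, spec$d_iso)
  attr(pred, "dw_index") <- which(!scheme$b0_mask)
  expect_lt(energy(pred, dwi), 1e-10)
})

test_that("with noise, every bundle's fibers carry signal", {
  ph <- cached_phantom()
  scheme <- ph$scheme
  base <- free_water_baseline(ph$tissue, scheme, ph$spec$d_iso)
  dw <- which(!scheme$b0_mask)
  e_of <- function(weights) {
    pred <- predict_signal(spline_set(ph$truth$splines, weights),
                           ph$tissue, scheme) + base
    attr(pred, "dw_index") <- dw
    energy(pred, ph$dwi)
  }
  e_true <- e_of(ph$truth$weights)
  for (b in seq_along(ph$truth$splines)) {
    w <- ph$truth$weights
    w[b] <- 0
    expect_gt(e_of(w), e_true)
  }
})
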