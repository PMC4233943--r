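test_that("endpoint extension reaches GM or rejects the streamline", {
  tis <- straight_tissue()
  vs <- 3
  yc <- floor(dim(tis$gm_labels)[2] / 2) * vs
  zm <- floor(dim(tis$gm_labels)[3] / 2) * vs
  nx <- dim(tis$gm_labels)[1]

  # both endpoints already in GM: unchanged
  full <- cbind(seq(2 * vs, (nx - 2) * vs, length.out = 20), yc, zm)
  expect_equal(extend_to_gm(full, tis), full)

  # endpoint stopping one voxel short of GM gets extended into it
  short <- cbind(seq(2 * vs, (nx - 4) * vs, length.out = 20), yc, zm)
  ext <- extend_to_gm(short, tis)
  expect_false(is.null(ext))
  expect_gt(nrow(ext), nrow(short))
  ends <- classify_point(ext[c(1, nrow(ext)), ], tis)
  expect_true(all(ends > 0))

  # endpoint two voxels from any GM: rejected
  far <- cbind(seq(2 * vs, (nx - 5) * vs, length.out = 20), yc, zm)
  expect_null(extend_to_gm(far, tis))
})

test_that("filtering keeps exactly the GM-to-GM streamlines", {
  tis <- straight_tissue()
  vs <- 3
  yc <- floor(dim(tis$gm_labels)[2] / 2) * vs
  zm <- floor(dim(tis$gm_labels)[3] / 2) * vs
  nx <- dim(tis$gm_labels)[1]
  good <- cbind(seq(2 * vs, (nx - 2) * vs, length.out = 20), yc, zm)
  extendable <- cbind(seq(2 * vs, (nx - 4) * vs, length.out = 20), yc, zm)
  premature <- cbind(seq(5 * vs, (nx - 6) * vs, length.out = 10), yc, zm)
  background <- cbind(seq(0, 20, length.out = 5), 0, 0)
  tract <- tractogram(list(good, extendable, premature, background,
                           good + c(0, 0, 0)))
  out <- filter_library(tract, tis)
  expect_length(out$streamlines, 3)
  for (s in out$streamlines)
    expect_true(all(classify_point(s[c(1, nrow(s)), ], tis) > 0))

  # nothing survives -> empty tractogram with a warning
  expect_warning(empty <- filter_library(tractogram(list(premature)), tis),
                 "no streamline")
  expect_length(empty$streamlines, 0)
})

test_that("MDF distance is flip-invariant and clustering merges duplicates", {
  set.seed(41)
  a <- resample_polyline(matrix(c(0, 0, 0, 10, 3, 1, 20, 0, 0), 3, 3,
                                byrow = TRUE), 25)
  expect_equal(mdf_distance(a, a[25:1, ]), 0, tolerance = 1e-12)

  b <- sweep(a, 2, c(0, 10, 0), `+`)
  expect_equal(mdf_distance(a, b), 10, tolerance = 1e-9)

  # duplicates merge; distant streamlines stay separate
  tr <- tractogram(list(a, a, b))
  out <- cluster_streamlines(tr, threshold = 3, n_points = 25)
  expect_length(out$streamlines, 2)
  expect_equal(attr(out, "cluster_sizes"), c(2L, 1L))

  # a flipped copy joins the same cluster
  out2 <- cluster_streamlines(tractogram(list(a, a[25:1, ])), threshold = 3)
  expect_length(out2$streamlines, 1)

  # below-threshold neighbors merge into a representative between them
  c2 <- sweep(a, 2, c(0, 1, 0), `+`)
  out3 <- cluster_streamlines(tractogram(list(a, c2)), threshold = 3)
  expect_length(out3$streamlines, 1)
  expect_equal(out3$streamlines[[1]], (resample_polyline(a, 25) +
                                       resample_polyline(c2, 25)) / 2,
               tolerance = 1e-9)
})

test_that("initial weight calibration recovers the generating weight", {
  spec <- straight_phantom_spec(snr = Inf, weight = 0.3, d_iso = 0)
  ph <- generate_phantom(spec)
  fibers <- spline_set(ph$truth$splines)
  w <- calibrate_initial_weight(fibers, ph$dwi, ph$tissue, d_iso = 0)
  expect_equal(as.numeric(w), 0.3, tolerance = 1e-3)

  # with the free-water background present and modeled
  spec2 <- straight_phantom_spec(snr = Inf, weight = 0.3, d_iso = 2)
  ph2 <- generate_phantom(spec2)
  w2 <- calibrate_initial_weight(fibers, ph2$dwi, ph2$tissue, d_iso = 2)
  expect_equal(as.numeric(w2), 0.3, tolerance = 1e-3)

  # grid argmin agrees with the closed form within one grid step
  scan <- attr(w, "scan")
  w_grid <- scan$weight[which.min(scan$energy)]
  step <- (1 / 1e-5)^(1 / 63)
  expect_lt(max(w_grid / as.numeric(w), as.numeric(w) / w_grid), step * 1.01)

  # duplicating every fiber halves the calibrated weight (linearity)
  dup <- spline_set(c(fibers$control, fibers$control))
  wd <- calibrate_initial_weight(dup, ph$dwi, ph$tissue, d_iso = 0)
  expect_equal(as.numeric(wd), 0.15, tolerance = 1e-3)

  # invariant to fiber order
  ph3 <- cached_phantom()
  f3 <- spline_set(ph3$truth$splines)
  f3r <- spline_set(rev(ph3$truth$splines))
  expect_equal(as.numeric(calibrate_initial_weight(f3, ph3$dwi, ph3$tissue)),
               as.numeric(calibrate_initial_weight(f3r, ph3$dwi,
                                                   ph3$tissue)),
               tolerance = 1e-12)

  # an all-zero prediction cannot be calibrated
  off_grid <- spline_set(list(cbind(seq(500, 600, length.out = 7), 0, 0)))
  expect_error(calibrate_initial_weight(off_grid, ph$dwi, ph$tissue),
               "all-zero")
})

test_that("tissue projection snaps grazing control points into the mask", {
  tis <- straight_tissue()
  vs <- 3
  yc <- floor(dim(tis$gm_labels)[2] / 2) * vs
  zm <- floor(dim(tis$gm_labels)[3] / 2) * vs
  nx <- dim(tis$gm_labels)[1]
  good <- cbind(seq(2 * vs, (nx - 2) * vs, length.out = 7), yc, zm)
  expect_equal(project_to_tissue(good, tis), good)   # already valid: no-op

  # an interior point one voxel outside the tube gets pulled back in
  off <- good
  off[4, 2] <- yc + 2 * vs
  proj <- project_to_tissue(off, tis)
  expect_true(check_anatomical_validity(proj, tis))
  expect_equal(proj[-4, ], good[-4, ])
  # an endpoint just outside gray matter gets snapped onto it
  off2 <- good
  off2[1, 1] <- 0.5 * vs
  proj2 <- project_to_tissue(off2, tis)
  expect_gt(classify_point(proj2[1, ], tis), 0)
})

test_that("prepared libraries are anatomically valid end to end", {
  ph <- cached_phantom()
  cand <- track_candidates(ph$dwi, ph$tissue)
  fib <- prepare_library(cand, ph$dwi, ph$tissue)
  expect_gt(length(fib$control), 0)
  expect_true(all(check_anatomical_validity(fib, ph$tissue)))
  expect_true(all(fib$weights > 0 & fib$weights <= 1))
  # every streamline that survives filtering ends in GM (anatomical prior)
  filt <- filter_library(cand, ph$tissue)
  cls <- vapply(filt$streamlines, function(s)
    all(classify_point(s[c(1, nrow(s)), ], ph$tissue) > 0), TRUE)
  expect_true(all(cls))
})
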