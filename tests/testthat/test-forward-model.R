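test_that("segment attenuation matches closed forms and rotation oracle", {
  seg <- data.frame(mx = 0, my = 0, mz = 0, dx = 1, dy = 0, dz = 0,
                    length = 2)
  # b = 0 at the segment midpoint: both factors are 1
  expect_equal(segment_attenuation(seg, c(0, 0, 0), c(1, 0, 0), 0), 1.0)

  # perpendicular gradient, FiberCup tensor at b = 1500: exp(-1.5 * 0.85)
  expect_equal(segment_attenuation(seg, c(0, 0, 0), c(0, 1, 0), 1500),
               exp(-1.275), tolerance = 1e-12)
  # parallel gradient: exp(-1.5 * 2.1)
  expect_equal(segment_attenuation(seg, c(0, 0, 0), c(1, 0, 0), 1500),
               exp(-3.15), tolerance = 1e-12)

  # arbitrary oblique geometry against the explicit R diag(lambda) R' oracle
  set.seed(21)
  for (i in 1:25) {
    nseg <- rnorm(3); nseg <- nseg / sqrt(sum(nseg^2))
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    mid <- rnorm(3, sd = 5); x <- mid + rnorm(3, sd = 1)
    b <- runif(1, 500, 3000)
    got <- segment_attenuation(list(mx = mid[1], my = mid[2], mz = mid[3],
                                    dx = nseg[1], dy = nseg[2],
                                    dz = nseg[3]),
                               x, n, b, sigma = 0.5, voxel_size = 3)
    want <- oracle_segment_attenuation(mid, nseg, x, n, b,
                                       c(2.1, 0.85, 0.85), 0.5,
                                       voxel_size = 3)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("predicted signal is linear and matches the brute-force oracle", {
  tis <- straight_tissue(nx = 10, ny = 7, nz = 3)
  scheme <- phantom_scheme(12, 1500)
  params <- forward_params()
  vs <- tis$voxel_size[1]
  zm <- floor(dim(tis$gm_labels)[3] / 2) * vs
  yc <- floor(dim(tis$gm_labels)[2] / 2) * vs
  set.seed(22)
  mk_fiber <- function() {
    x <- sort(runif(7, 1.5 * vs, (dim(tis$gm_labels)[1] - 2.5) * vs))
    cbind(x, yc + rnorm(7, sd = 1.5), zm + rnorm(7, sd = 0.5))
  }
  fibers <- spline_set(replicate(3, mk_fiber(), simplify = FALSE),
                       c(0.3, 0.5, 0.2))

  # empty configuration predicts zero
  empty <- spline_set(list(), numeric(0))
  expect_true(all(predict_signal(empty, tis, scheme, params) == 0))

  # doubling one weight doubles exactly that fiber's contribution
  one <- spline_set(fibers$control[1], 0.3)
  two <- spline_set(fibers$control[1], 0.6)
  expect_equal(predict_signal(two, tis, scheme, params),
               2 * predict_signal(one, tis, scheme, params),
               tolerance = 1e-12, ignore_attr = TRUE)

  # 3-fiber configuration vs untruncated triple-loop oracle
  pred <- predict_signal(fibers, tis, scheme, params)
  want <- oracle_predict(fibers, dim(tis$gm_labels), tis$affine, scheme,
                         params)
  expect_lt(max(abs(pred - want)), 1e-4)   # kernel truncation error bound
})

test_that("energy matches closed forms and the naive summation oracle", {
  scheme <- phantom_scheme(5, 1500)
  dims <- c(4, 3, 2)
  G <- nrow(scheme$directions)
  set.seed(23)
  data <- attenuation_volume(array(runif(prod(dims) * G), c(dims, G)),
                             scheme, diag(4))
  dw <- which(!scheme$b0_mask)
  pred0 <- array(data$data[, , , dw], c(dims, length(dw)))
  attr(pred0, "dw_index") <- dw
  mask <- array(TRUE, dims)

  expect_equal(energy(pred0, data, mask), 0)

  # prediction = data + 1 on V voxels, G_dw directions -> V * G_dw
  pred1 <- pred0 + 1
  attr(pred1, "dw_index") <- dw
  expect_equal(energy(pred1, data, mask), prod(dims) * length(dw))

  # random pair vs naive two-loop oracle, random mask
  predr <- pred0 + array(rnorm(length(pred0)), dim(pred0))
  attr(predr, "dw_index") <- dw
  maskr <- array(runif(prod(dims)) > 0.4, dims)
  expect_equal(energy(predr, data, maskr),
               oracle_energy(predr, data, maskr), tolerance = 1e-10)

  expect_error(energy(pred0[1:2, , , , drop = FALSE], data, mask),
               "shape mismatch")
})

test_that("NMSE map handles perfect, null and hand-computed predictions", {
  scheme <- gradient_scheme(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            c(0, 1500, 1500))
  dims <- c(2, 2, 1)
  arr <- array(1, c(dims, 3))
  data <- attenuation_volume(arr, scheme, diag(4))
  dw <- 2:3
  perfect <- array(1, c(dims, 2)); attr(perfect, "dw_index") <- dw
  expect_true(all(nmse_map(perfect, data) == 0))

  null <- array(0, c(dims, 2)); attr(null, "dw_index") <- dw
  expect_true(all(nmse_map(null, data) == 1))

  # voxel with D = (1, 1) and prediction (1, 0): NMSE = 1/2
  pred <- perfect; pred[1, 1, 1, 2] <- 0
  expect_equal(nmse_map(pred, data)[1, 1, 1], 0.5)

  # zero data norm -> undefined voxel
  arr0 <- arr; arr0[2, 2, 1, dw] <- 0
  data0 <- attenuation_volume(arr0, scheme, diag(4))
  expect_true(is.na(nmse_map(perfect, data0)[2, 2, 1]))
})

test_that("prediction is invariant to fiber order and direction flips", {
  tis <- straight_tissue(nx = 10, ny = 7, nz = 3)
  scheme <- phantom_scheme(8, 1500)
  set.seed(24)
  vs <- 3
  f1 <- cbind(sort(runif(7, 4, 24)), 9 + rnorm(7), 3 + rnorm(7, sd = .3))
  f2 <- cbind(sort(runif(7, 4, 24)), 9 + rnorm(7), 3 + rnorm(7, sd = .3))
  a <- predict_signal(spline_set(list(f1, f2), c(.2, .4)), tis, scheme)
  b <- predict_signal(spline_set(list(f2, f1), c(.4, .2)), tis, scheme)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
  # reversing a fiber's control points leaves the prediction unchanged
  c2 <- predict_signal(spline_set(list(f1, f2[7:1, ]), c(.2, .4)), tis,
                       scheme)
  expect_equal(a, c2, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("incremental configuration updates stay consistent with recomputation", {
  tis <- straight_tissue(nx = 12, ny = 7, nz = 3)
  scheme <- phantom_scheme(10, 1500)
  params <- forward_params()
  set.seed(25)
  mk_fiber <- function()
    cbind(sort(runif(7, 4, 30)), 9 + rnorm(7, sd = 1.5), 3 + rnorm(7, sd = .4))
  fibers <- spline_set(replicate(4, mk_fiber(), simplify = FALSE),
                       runif(4, 0.1, 0.6))
  arr <- array(runif(prod(dim(tis$gm_labels)) * nrow(scheme$directions),
                     0, 0.3), c(dim(tis$gm_labels), nrow(scheme$directions)))
  data <- attenuation_volume(arr, scheme, tis$affine)
  cfg <- fiber_configuration(fibers, data, mask = NULL, params = params)

  # construction is already consistent
  expect_lt(audit_configuration(cfg)$rel_diff, 1e-8)

  # weight change to the same value is a no-op
  cfg2 <- update_configuration(cfg, "weight", fiber = 1,
                               weight = cfg$fibers$weights[1])
  expect_equal(cfg2$energy, cfg$energy)
  expect_equal(cfg2$pred, cfg$pred)

  # remove then re-add the same fiber restores the energy
  ctrl1 <- cfg$fibers$control[[1]]; w1 <- cfg$fibers$weights[1]
  cfg3 <- update_configuration(cfg, "remove", fiber = 1)
  cfg3 <- update_configuration(cfg3, "add", control = ctrl1, weight = w1)
  expect_equal(cfg3$energy, cfg$energy, tolerance = 1e-9)

  # 100 random updates, then audit against full recomputation
  set.seed(26)
  for (i in 1:100) {
    nf <- length(cfg$fibers$control)
    op <- sample(c("weight", "move", "add", "remove"), 1,
                 prob = c(.4, .4, .15, .05))
    if (nf == 0) op <- "add"
    if (nf == 1 && op == "remove") op <- "weight"
    f <- sample(nf, 1)
    cfg <- switch(op,
      weight = update_configuration(cfg, "weight", fiber = f,
                                    weight = runif(1)),
      move = update_configuration(cfg, "move", fiber = f,
        control = cfg$fibers$control[[f]] +
          matrix(rnorm(21, sd = 0.5), 7, 3)),
      add = update_configuration(cfg, "add", control = mk_fiber(),
                                 weight = runif(1)),
      remove = update_configuration(cfg, "remove", fiber = f))
  }
  audit <- audit_configuration(cfg)
  expect_lt(audit$rel_diff, 1e-6)
})
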