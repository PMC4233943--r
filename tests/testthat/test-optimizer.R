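test_that("Metropolis acceptance follows the annealing criterion", {
  # a lower-energy candidate is always accepted
  expect_true(accept(10, 5, 1e-9))
  expect_true(accept(10, 10, 0.5, u = 0.999))
  # near-zero temperature rejects every uphill move
  expect_false(accept(5, 10, 1e-12, u = 1e-9))
  expect_error(accept(1, 2, 0), "> 0")

  # dE = T ln 2: acceptance probability exactly 1/2
  T <- 0.37
  dE <- T * log(2)
  set.seed(51)
  u <- runif(1e5)
  rate <- mean(vapply(u, function(ui) accept(0, dE, T, u = ui), TRUE))
  expect_equal(rate, 0.5, tolerance = 0.01)
})

test_that("proposal frequencies match the configured 40/40/15/5 split", {
  ph <- cached_phantom()
  fib <- spline_set(ph$truth$splines, ph$truth$weights)
  fit <- gtract_fit(ph$dwi, ph$tissue, fib,
                    control = sa_control(n_iter = 1e5, trace_every = 0,
                                         audit_every = 0,
                                         planar_moves = TRUE),
                    seed = 7)
  freq <- fit$proposal_counts / sum(fit$proposal_counts)
  expect_lt(max(abs(freq - c(0.40, 0.40, 0.15, 0.05))), 0.01)
})

test_that("annealing is deterministic given a seed", {
  ph <- cached_phantom()
  fib <- spline_set(ph$truth$splines, rep(0.4, 7))
  base <- free_water_baseline(ph$tissue, ph$dwi$scheme, ph$spec$d_iso)
  f1 <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                   control = sa_control(n_iter = 3000), seed = 123)
  f2 <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                   control = sa_control(n_iter = 3000), seed = 123)
  expect_identical(f1$fibers$weights, f2$fibers$weights)
  expect_identical(f1$fibers$control, f2$fibers$control)
  expect_identical(f1$trace, f2$trace)
  f3 <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                   control = sa_control(n_iter = 3000), seed = 124)
  expect_false(identical(f1$fibers$weights, f3$fibers$weights))
})

test_that("near-zero temperature gives greedy descent", {
  ph <- cached_phantom()
  fib <- spline_set(ph$truth$splines, rep(0.4, 7))
  base <- free_water_baseline(ph$tissue, ph$dwi$scheme, ph$spec$d_iso)
  fit <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                    control = sa_control(n_iter = 5000, t_start = 1e-12,
                                         t_end_frac = 1, trace_every = 100),
                    seed = 3)
  expect_true(all(diff(fit$trace$energy) <= 1e-9))
  expect_lte(fit$final_energy, fit$initial_energy)
})

test_that("the best-visited energy is a running minimum of the trace", {
  ph <- cached_phantom()
  fib <- spline_set(ph$truth$splines, rep(0.4, 7))
  base <- free_water_baseline(ph$tissue, ph$dwi$scheme, ph$spec$d_iso)
  fit <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                    control = sa_control(n_iter = 8000, trace_every = 200),
                    seed = 5)
  run_min <- cummin(fit$trace$energy)
  expect_true(all(diff(run_min) <= 0))
  expect_lte(fit$best_energy, min(fit$trace$energy) + 1e-9)
  expect_lte(fit$best_energy, fit$initial_energy)
})

test_that("every fiber remains anatomically valid after optimization", {
  ph <- cached_phantom()
  fib <- spline_set(ph$truth$splines, rep(0.4, 7))
  base <- free_water_baseline(ph$tissue, ph$dwi$scheme, ph$spec$d_iso)
  fit <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                    control = sa_control(n_iter = 2e4), seed = 9)
  expect_true(all(check_anatomical_validity(fit$fibers, ph$tissue)))
  expect_true(all(check_anatomical_validity(fit$last_fibers, ph$tissue)))
  expect_true(all(fit$fibers$weights >= 0 & fit$fibers$weights <= 1))
  # an invalid initial fiber is refused
  bad <- fib
  bad$control[[1]][4, ] <- c(0, 0, 0)
  expect_error(gtract_fit(ph$dwi, ph$tissue, bad), "violate")
  expect_error(gtract_fit(ph$dwi, ph$tissue,
                          spline_set(list(), numeric(0))), "empty")
})

test_that("the smoothness constraint rejects folded fibers", {
  straight <- cbind(seq(0, 30, 5), 0, 0)
  expect_lt(max_chord_turn(straight), 1)
  folded <- cbind(c(0, 5, 10, 8, 3, 8, 13), c(0, 0, 0, 1, 2, 3, 3), 0)
  expect_gt(max_chord_turn(folded), 90)
  # phantom ground truth is comfortably within the bound
  ph <- cached_phantom()
  expect_true(all(max_chord_turn(spline_set(ph$truth$splines)) < 60))
  # an initial fiber violating the bound is refused outright
  tis <- straight_tissue()
  vs <- 3; yc <- floor(dim(tis$gm_labels)[2] / 2) * vs
  zm <- floor(dim(tis$gm_labels)[3] / 2) * vs
  nx <- dim(tis$gm_labels)[1]
  zig <- cbind(c(2, 4, 6, 5, 7, 10, nx - 2) * vs,
               yc + c(0, 2, -2, 2, -2, 2, 0), zm)
  arr <- array(0.1, c(dim(tis$gm_labels), 9))
  sch <- phantom_scheme(8, 1500)
  dat <- attenuation_volume(arr, sch, tis$affine)
  if (check_anatomical_validity(zig, tis) && max_chord_turn(zig) > 90)
    expect_error(gtract_fit(dat, tis, spline_set(list(zig), 0.5)),
                 "turn angle")
})

test_that("single-fiber weight recovery on the noiseless phantom", {
  spec <- straight_phantom_spec(snr = Inf, weight = 0.3, d_iso = 0)
  ph <- generate_phantom(spec)
  # start from the true geometry at a wrong weight; weight proposals only
  fib <- spline_set(ph$truth$splines, 0.9)
  fit <- gtract_fit(ph$dwi, ph$tissue, fib,
                    control = sa_control(n_iter = 2e4, probs = c(1, 0, 0, 0)),
                    seed = 11)
  expect_equal(fit$fibers$weights, 0.3, tolerance = 0.05)
  expect_lt(fit$best_energy, fit$initial_energy)
})

test_that("fit accessors are coherent with the forward model", {
  ph <- cached_phantom()
  fib <- spline_set(ph$truth$splines, rep(0.4, 7))
  base <- free_water_baseline(ph$tissue, ph$dwi$scheme, ph$spec$d_iso)
  fit <- gtract_fit(ph$dwi, ph$tissue, fib, baseline = base,
                    control = sa_control(n_iter = 2000), seed = 13)
  expect_length(coef(fit), length(fit$fibers$control))
  pred <- fitted(fit)
  expect_equal(dim(pred), c(dim(ph$tissue$gm_labels), 64))
  # reported energy matches an independent recomputation
  e <- energy(pred + base, ph$dwi)
  expect_equal(e, fit$best_energy, tolerance = 1e-8)
  r <- residuals(fit)
  expect_equal(dim(r), dim(pred))
  expect_equal(as.vector(ph$dwi$data[, , , -1] - (pred + base)),
               as.vector(r), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1, snr = 20)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "attenuation_volume")
})
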