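test_that("Douglas-Peucker reduction keeps endpoints and salient points", {
  # collinear polyline to 2 points: exactly the endpoints
  line <- cbind(seq(0, 24, length.out = 25), 0, 0)
  expect_equal(douglas_peucker_reduce(line, 2), line[c(1, 25), ])

  # V shape to 3 points: endpoints + apex (exhaustive max-deviation check)
  v <- rbind(cbind(seq(0, 10, length.out = 11), seq(0, 10, length.out = 11)),
             cbind(seq(11, 20, length.out = 10), seq(9, 0, length.out = 10)))
  v3 <- cbind(v, 0)
  red <- douglas_peucker_reduce(v3, 3)
  dists <- line_dist_oracle <- apply(v3, 1, function(p) {
    a <- v3[1, ]; b <- v3[nrow(v3), ]
    d <- b - a
    sqrt(sum((p - a - sum((p - a) * d) / sum(d^2) * d)^2))
  })
  apex <- v3[which.max(dists), ]
  expect_equal(red, rbind(v3[1, ], apex, v3[nrow(v3), ]),
               ignore_attr = TRUE)

  # any input: output is an ordered subsequence including both endpoints
  set.seed(3)
  for (i in 1:10) {
    pts <- cbind(cumsum(runif(30, 0.5, 2)), rnorm(30), rnorm(30))
    k <- sample(2:10, 1)
    red <- douglas_peucker_reduce(pts, k)
    expect_equal(nrow(red), k)
    idx <- apply(red, 1, function(p)
      which(apply(pts, 1, function(q) all(abs(q - p) < 1e-12)))[1])
    expect_false(any(is.na(idx)))
    expect_true(all(diff(idx) > 0))
    expect_equal(idx[1], 1)
    expect_equal(idx[k], 30)
  }

  # shorter input than target: padded, endpoints preserved
  short <- cbind(c(0, 5, 10), 0, 0)
  expect_message(out <- douglas_peucker_reduce(short, 5), "padded")
  expect_equal(nrow(out), 5)
  expect_equal(out[1, ], short[1, ])
  expect_equal(out[5, ], short[3, ])
})

test_that("Catmull-Rom evaluation interpolates control points exactly", {
  set.seed(5)
  ctrl <- matrix(rnorm(21, sd = 10), 7, 3)
  knots <- seq(0, 1, length.out = 7)
  expect_equal(catmull_rom_evaluate(ctrl, knots), ctrl, tolerance = 1e-12)

  # collinear control points stay on the line (affine invariance)
  t <- seq(0, 1, 0.01)
  lin <- cbind(seq(0, 6, 1), 2 * seq(0, 6, 1), -seq(0, 6, 1))
  pts <- catmull_rom_evaluate(lin, t)
  expect_equal(pts[, 2], 2 * pts[, 1], tolerance = 1e-10)
  expect_equal(pts[, 3], -pts[, 1], tolerance = 1e-10)

  # t outside [0,1] clamps to the endpoints
  expect_equal(catmull_rom_evaluate(ctrl, c(-0.5, 1.5)),
               ctrl[c(1, 7), ], tolerance = 1e-12)
})

test_that("Catmull-Rom midpoints match the cardinal Hermite expansion", {
  # independent oracle: tau = 1/2 cardinal spline in Hermite form with
  # one-sided tangents at the (duplicated) ends
  set.seed(6)
  ctrl <- matrix(rnorm(21, sd = 5), 7, 3)
  hermite <- function(P, i, u) {
    n <- nrow(P)
    m_at <- function(j) {
      jm <- max(j - 1, 1); jp <- min(j + 1, n)
      (P[jp, ] - P[jm, ]) / 2
    }
    p0 <- P[i, ]; p1 <- P[i + 1, ]
    m0 <- m_at(i); m1 <- m_at(i + 1)
    h00 <- 2 * u^3 - 3 * u^2 + 1; h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2;    h11 <- u^3 - u^2
    h00 * p0 + h10 * m0 + h01 * p1 + h11 * m1
  }
  for (i in 1:6) {
    tmid <- (i - 1 + 0.5) / 6
    expect_equal(as.vector(catmull_rom_evaluate(ctrl, tmid)),
                 hermite(ctrl, i, 0.5), tolerance = 1e-12)
  }
})

test_that("discretization produces equal-arc-length segments", {
  # straight spline of length 30 mm at 2 mm segments -> 15 collinear segments
  line <- cbind(seq(0, 30, length.out = 7), 0, 0)
  segs <- discretize(line, 2)
  expect_equal(nrow(segs), 15)
  expect_equal(unique(round(segs$length, 9)), 2)
  expect_true(all(abs(segs$dx - 1) < 1e-9))
  expect_true(all(abs(segs$dy) < 1e-9 & abs(segs$dz) < 1e-9))

  # curved spline: total segment length matches dense-quadrature arc length
  set.seed(8)
  ctrl <- matrix(rnorm(21, sd = 8), 7, 3)
  segs <- discretize(ctrl, 2)
  L <- oracle_arc_length(ctrl)
  expect_equal(sum(segs$length), L, tolerance = 5e-3)
  expect_lt(max(segs$length), 2 + 0.01)

  # degenerate: spline shorter than one segment -> a single segment
  tiny <- cbind(c(0, 0.5), 0, 0)
  expect_equal(nrow(discretize(tiny, 2)), 1)
})

test_that("reversing a spline flips segment directions but not attenuations", {
  set.seed(9)
  ctrl <- matrix(rnorm(21, sd = 8), 7, 3)
  a <- discretize(ctrl, 2)
  b <- discretize(ctrl[7:1, ], 2)
  expect_equal(nrow(a), nrow(b))
  # same midpoints in reverse order, antipodal directions
  expect_equal(as.matrix(a[, 1:3]), as.matrix(b[nrow(b):1, 1:3]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.matrix(a[, 4:6]), -as.matrix(b[nrow(b):1, 4:6]),
               tolerance = 1e-4, ignore_attr = TRUE)
  # n' D n is even in n: attenuation identical under the flip
  n <- c(1, 2, 2) / 3
  att_a <- segment_attenuation(a[1, ], c(0, 0, 0), n, 1500)
  att_b <- segment_attenuation(data.frame(mx = a$mx[1], my = a$my[1],
                                          mz = a$mz[1], dx = -a$dx[1],
                                          dy = -a$dy[1], dz = -a$dz[1]),
                               c(0, 0, 0), n, 1500)
  expect_equal(att_a, att_b, tolerance = 1e-12)
})

test_that("anatomical validity checks endpoints-in-GM, interior-in-WM", {
  tis <- straight_tissue()
  vs <- tis$voxel_size[1]
  zm <- floor(dim(tis$gm_labels)[3] / 2)
  yc <- floor(dim(tis$gm_labels)[2] / 2)
  nx <- dim(tis$gm_labels)[1]
  good <- cbind(seq(2, nx - 2, length.out = 7) * vs, yc * vs, zm * vs)
  expect_true(check_anatomical_validity(good, tis))

  # an interior control point in GM invalidates the fiber
  bad_gm <- good; bad_gm[3, 1] <- 2 * vs
  expect_false(check_anatomical_validity(bad_gm, tis))

  # an endpoint outside the tissue invalidates the fiber
  bad_out <- good; bad_out[7, ] <- c(-10, -10, -10)
  expect_false(check_anatomical_validity(bad_out, tis))

  # vectorized over a spline_set
  expect_equal(check_anatomical_validity(
    spline_set(list(good, bad_gm, bad_out)), tis), c(TRUE, FALSE, FALSE))
})

test_that("spline reduction of a dense spline sampling recovers shape", {
  set.seed(10)
  ctrl <- apply(matrix(rnorm(21, sd = 2), 7, 3), 2, cumsum) * 4
  dense <- catmull_rom_evaluate(ctrl, seq(0, 1, length.out = 400))
  red <- polyline_to_spline(dense, n_control = 7, n_resample = 25)
  # the re-fit spline stays close to the original curve
  orig <- catmull_rom_evaluate(ctrl, seq(0, 1, length.out = 100))
  refit <- catmull_rom_evaluate(red, seq(0, 1, length.out = 100))
  dmax <- max(sqrt(rowSums((orig - refit)^2)))
  expect_lt(dmax, 2)   # within one segment length
})
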