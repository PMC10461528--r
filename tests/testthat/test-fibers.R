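test_that("df = 1 smoothing is exactly the least-squares line fit", {
  set.seed(8)
  n <- 30
  t_true <- seq(0, 1, length.out = n)
  pts <- cbind(2 + 5 * t_true, -1 + 3 * t_true, 40 * t_true) +
    matrix(stats::rnorm(3 * n, 0, 0.3), n)
  f <- smooth_fiber(list(points = pts, gray = rep(0.8, n)), df = 1)
  # closed-form regression oracle on the chord-length parameter
  seg <- sqrt(rowSums(diff(pts)^2))
  tt <- c(0, cumsum(seg)) / sum(seg)
  co <- stats::lm.fit(cbind(1, tt), pts)$coefficients
  expect_equal(unname(f$dense_points[1, ]), unname(co[1, ] + 0 * co[2, ]),
               tolerance = 1e-8)
  expect_equal(unname(f$dense_points[nrow(f$dense_points), ]),
               unname(co[1, ] + 1 * co[2, ]), tolerance = 1e-8)
  resid_oracle <- mean(sqrt(rowSums((pts - cbind(1, tt) %*% co)^2)))
  expect_equal(f$mean_residual, resid_oracle, tolerance = 1e-8)
  # dense points are collinear
  d <- f$dense_points
  dirs <- diff(d); dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_lt(max(abs(sweep(dirs, 2, dirs[1, ]))), 1e-8)
})

test_that("collinear input smooths to a zero-residual straight line", {
  pts <- cbind(1:20, 2 * (1:20), 3 * (1:20))
  f <- smooth_fiber(list(points = pts, gray = rep(0.5, 20)), df = 1)
  expect_equal(f$mean_residual, 0, tolerance = 1e-10)
  expect_equal(fiber_tortuosity(f), 1, tolerance = 1e-10)
})

test_that("noisy straight tracks recover the line direction within 5 degrees", {
  set.seed(9)
  truth_dir <- c(1, 2, 10) / sqrt(105)
  pts <- t(sapply(seq(0, 50, length.out = 60), function(s) s * truth_dir)) +
    matrix(stats::rnorm(180, 0, 0.5), 60)
  f <- smooth_fiber(list(points = pts, gray = rep(0.8, 60)), df = 1)
  d <- f$dense_points
  fit_dir <- d[nrow(d), ] - d[1, ]
  fit_dir <- fit_dir / sqrt(sum(fit_dir^2))
  ang <- acos(abs(sum(fit_dir * truth_dir))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("semicircle smoothing reproduces the analytic arc length", {
  th <- seq(0, pi, length.out = 40)
  pts <- cbind(20 * cos(th), 20 * sin(th), 0)
  f <- smooth_fiber(list(points = pts, gray = rep(0.8, 40)), df = 3)
  expect_lt(abs(fiber_length(f) - 20 * pi) / (20 * pi), 0.02)
  expect_error(smooth_fiber(list(points = pts[1:3, ], gray = rep(0.8, 3)), 3),
               "too few")
})

test_that("quality_check removes ratio outliers and short fibers, idempotently", {
  mk <- function(len, qr, id) {
    f <- fake_fiber(cbind(0, 0, seq(0, len, length.out = 50)), id)
    f$quality_ratio <- qr
    f
  }
  same <- fake_set(lapply(1:20, function(i) mk(50, 0.001, i)))
  expect_equal(length(quality_check(same)$fibers), 20L)
  mixed <- fake_set(c(lapply(1:19, function(i) mk(50, 0.001, i)),
                      list(mk(50, 0.5, 20L))))
  kept <- quality_check(mixed)
  expect_equal(length(kept$fibers), 19L)
  expect_false(any(vapply(kept$fibers, `[[`, 0, "quality_ratio") > 0.4))
  lens <- fake_set(list(mk(10, 1e-3, 1L), mk(50, 1e-3, 2L), mk(60, 1e-3, 3L)))
  expect_equal(length(quality_check(lens, min_length = 30)$fibers), 2L)
  # idempotence
  once <- quality_check(mixed)
  twice <- quality_check(once)
  expect_equal(vapply(twice$fibers, `[[`, 0L, "id"),
               vapply(once$fibers, `[[`, 0L, "id"))
})

test_that("fuse_fibers joins collinear halves and rejects bad merges", {
  half1 <- list(points = cbind(0, 0, seq(0, 20, 1)), gray = rep(0.8, 21))
  half2 <- list(points = cbind(0, 0, seq(22, 42, 1)), gray = rep(0.8, 21))
  s <- fake_set(list(smooth_fiber(half1, 1, 1L), smooth_fiber(half2, 1, 2L)))
  fused <- fuse_fibers(s, min_vox = 8, df = 1)
  expect_equal(length(fused$fibers), 1L)
  expect_equal(fiber_length(fused$fibers[[1]]), 42, tolerance = 0.5)
  # perpendicular tracks meeting at endpoints: the df=1 merge fits badly
  perp1 <- list(points = cbind(seq(0, 20, 1), 0, 0), gray = rep(0.8, 21))
  perp2 <- list(points = cbind(20, seq(1, 21, 1), 0), gray = rep(0.8, 21))
  sp <- fake_set(list(smooth_fiber(perp1, 1, 1L), smooth_fiber(perp2, 1, 2L)))
  expect_equal(length(fuse_fibers(sp, min_vox = 8, df = 1)$fibers), 2L)
  # far apart: the distance gate blocks the pair
  far <- list(points = cbind(0, 40, seq(0, 20, 1)), gray = rep(0.8, 21))
  sf <- fake_set(list(smooth_fiber(half1, 1, 1L), smooth_fiber(far, 1, 2L)))
  expect_equal(length(fuse_fibers(sf, min_vox = 8, df = 1)$fibers), 2L)
  # idempotence and length monotonicity
  again <- fuse_fibers(fused, min_vox = 8, df = 1)
  expect_equal(length(again$fibers), 1L)
  expect_gte(max(vapply(fused$fibers, fiber_length, 0)),
             max(vapply(s$fibers, fiber_length, 0)))
})

test_that("check_overlap drops redundant fibers and keeps the longest", {
  long <- fake_fiber(cbind(0, 0, seq(0, 55, length.out = 100)), 1L)
  dup <- fake_fiber(cbind(0.3, 0, seq(0.5, 54, length.out = 100)), 2L)
  short_same <- fake_fiber(cbind(0.5, 0.5, seq(5, 45, length.out = 80)), 3L)
  parallel_far <- fake_fiber(cbind(30, 0, seq(0, 55, length.out = 100)), 4L)
  s <- fake_set(list(short_same, dup, long, parallel_far))
  kept <- check_overlap(s, min_vox = 8)
  expect_equal(sort(vapply(kept$fibers, `[[`, 0L, "id")), c(1L, 4L))
  # parallel tubes 3*min_vox apart are both retained
  s2 <- fake_set(list(long, parallel_far))
  expect_equal(length(check_overlap(s2, min_vox = 8)$fibers), 2L)
  # idempotence
  expect_equal(length(check_overlap(kept, min_vox = 8)$fibers), 2L)
})

test_that("realign translates coordinates and leaves metrics invariant", {
  f <- fake_fiber(cbind(1:30, 2, seq(0, 29)), 1L)
  s <- fake_set(list(f))
  s$offsets <- c(8, 8, 8)
  r <- realign(s)
  expect_equal(r$offsets, c(0, 0, 0))
  expect_equal(r$fibers[[1]]$dense_points[1, ], c(1 + 8, 2 + 8, 0 + 8))
  expect_equal(fiber_length(r$fibers[[1]]), fiber_length(f), tolerance = 1e-12)
  expect_equal(fiber_tortuosity(r$fibers[[1]]), fiber_tortuosity(f),
               tolerance = 1e-12)
  expect_equal(fiber_angle(r$fibers[[1]]), fiber_angle(f), tolerance = 1e-12)
  # identity offsets are a no-op
  s0 <- fake_set(list(f))
  expect_equal(realign(s0)$fibers[[1]]$dense_points, f$dense_points)
})
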