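test_that("tracking_config validates its ranges", {
  expect_s3_class(tracking_config(), "tracking_config")
  expect_error(tracking_config(threshold = 1.1), "threshold")
  expect_error(tracking_config(radius = 12), "radius")
  expect_error(tracking_config(radius = 0), "radius")
  expect_error(tracking_config(black_frac = 0), "black_frac")
  expect_warning(tracking_config(cutoff = 0.9, threshold = 0.5), "cutoff")
})

test_that("enumerate_endpoints equals brute-force lattice enumeration", {
  for (radius in 1:5) for (backstep in 0:2) for (direction in c(1L, -1L)) {
    got <- enumerate_endpoints(radius, backstep, direction)
    want <- oracle_endpoints(radius, backstep, direction)
    expect_equal(nrow(got), nrow(want),
                 info = sprintf("r=%d b=%d d=%d", radius, backstep, direction))
    expect_setequal(apply(got, 1, paste, collapse = ","),
                    apply(want, 1, paste, collapse = ","))
  }
  # hand-checked small cases
  expect_equal(unname(enumerate_endpoints(1, 0, 1L)), matrix(c(0, 0, 1), 1))
  expect_equal(nrow(enumerate_endpoints(2, 0, 1L)), 10L)
  e <- enumerate_endpoints(1, 1, 1L)
  expect_equal(nrow(e), 6L)
  expect_setequal(apply(e, 1, paste, collapse = ","),
                  c("0,0,1", "0,0,-1", "1,0,0", "-1,0,0", "0,1,0", "0,-1,0"))
  # monotone containment in the radius
  for (r in 1:4) {
    a <- apply(enumerate_endpoints(r, 0, 1L), 1, paste, collapse = ",")
    b <- apply(enumerate_endpoints(r + 1, 0, 1L), 1, paste, collapse = ",")
    expect_true(all(a %in% b))
  }
})

test_that("rasterize_segment is a symmetric DDA with Chebyshev+1 voxels", {
  expect_equal(rasterize_segment(c(0, 0, 0), c(0, 0, 3)),
               cbind(0, 0, 0:3))
  expect_equal(rasterize_segment(c(0, 0, 0), c(2, 0, 2)),
               cbind(0:2, 0, 0:2))
  set.seed(4)
  for (i in 1:50) {
    a <- sample(-10:10, 3, replace = TRUE)
    b <- sample(-10:10, 3, replace = TRUE)
    if (all(a == b)) next
    r <- rasterize_segment(a, b)
    expect_equal(r, oracle_raster(a, b))
    expect_equal(nrow(r), max(abs(b - a)) + 1)
    expect_equal(r[1, ], as.numeric(a))
    expect_equal(r[nrow(r), ], as.numeric(b))
    expect_true(all(abs(diff(r)) <= 1))
    expect_equal(r, rasterize_segment(b, a)[nrow(r):1, ])
    # integer translation invariance (needed for precomputed relative paths)
    sh <- sample(-5:5, 3, replace = TRUE)
    expect_equal(sweep(r, 2, -sh), rasterize_segment(a + sh, b + sh))
  }
  expect_error(rasterize_segment(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("path_gray_sd masks below cutoff and uses the sample SD", {
  st <- make_stack(4, 1, 4, function(x, y, z) c(0.8, 0.4, 0.6, 0.2)[x + 1])
  p <- path_gray_sd(st, cbind(0, 0, 0:2), cutoff = 0)
  expect_equal(p$gray_sd, stats::sd(c(0.8, 0.8, 0.8)))
  const <- make_stack(1, 1, 3, function(x, y, z) 0.8)
  p0 <- path_gray_sd(const, cbind(0, 0, 0:2), 0.5)
  expect_equal(p0$gray_sd, 0)
  expect_equal(p0$n_black, 0L)
  two <- make_stack(2, 1, 1, function(x, y, z) c(0.4, 0.6)[x + 1])
  p1 <- path_gray_sd(two, cbind(0:1, 0, 0), 0.5)
  expect_equal(p1$gray_sd, sqrt((0.3^2 + 0.3^2) / 1), tolerance = 1e-12)
  expect_equal(p1$n_black, 1L)
  dark <- make_stack(2, 1, 1, function(x, y, z) c(0.2, 0.3)[x + 1])
  p2 <- path_gray_sd(dark, cbind(0:1, 0, 0), 0.5)
  expect_equal(p2$gray_sd, 0)
  expect_equal(p2$n_black, 2L)
})

test_that("trajectory penalties lie in [1, 2] and reward the straight path", {
  ends <- rbind(c(0, 0, 5), c(3, 0, 4), c(0, 4, 3))
  tp <- trajectory_penalties(ends, c(0, 0, 0), c(0, 0, 1))
  expect_equal(tp$penalty[1], 1)           # on the trajectory
  expect_equal(max(tp$penalty), 2)         # worst deviator
  expect_true(all(tp$penalty >= 1 & tp$penalty <= 2))
  # first step: no trajectory, all penalties 1
  tp0 <- trajectory_penalties(ends, c(0, 0, 0), NULL)
  expect_equal(tp0$penalty, rep(1, 3))
  # all-equal deviations scale to 1
  sym <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1))
  tps <- trajectory_penalties(sym, c(0, 0, 0), c(0, 0, 1))
  expect_equal(tps$penalty, rep(1, 4))
})

test_that("diagnostic values scale SDs by the maximum and apply the penalty", {
  expect_equal(diagnostic_values(c(0.2, 0.4), c(1.7, 1.3), scalar = 0),
               c(0.5, 1))
  expect_equal(diagnostic_values(0.4, 1.5, 1), 1.5 * 1)
  expect_equal(diagnostic_values(c(0.2, 0.4), c(1.5, 1), 1), c(0.75, 1))
  expect_equal(diagnostic_values(c(0.2, 0.4), c(1.5, 1), 2), c(1.125, 1))
  expect_equal(diagnostic_values(c(0, 0), c(1, 2), 1), c(0, 0))
  expect_true(all(diagnostic_values(stats::runif(10), 1 + stats::runif(10), 2)
                  <= 2^2))
})

test_that("boundary_safe_mask equals naive erosion on a small volume", {
  a <- array(0, dim = c(12, 12, 12))
  a[3:10, 3:10, 3:10] <- 0.8
  st <- as_image_stack(a)
  for (b in c(1L, 2L)) {
    safe <- boundary_safe_mask(st, b)
    naive <- array(FALSE, dim = dim(a))
    sup <- a > 0
    for (x in 0:11) for (y in 0:11) for (z in 0:11) {
      if (!sup[y + 1, x + 1, z + 1]) next
      ok <- TRUE
      for (dx in -b:b) for (dy in -b:b) for (dz in -b:b) {
        if (dx^2 + dy^2 + dz^2 > b^2) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 0 || xx > 11 || yy < 0 || yy > 11 || zz < 0 || zz > 11 ||
            !sup[yy + 1, xx + 1, zz + 1]) { ok <- FALSE; break }
      }
      naive[y + 1, x + 1, z + 1] <- ok
    }
    expect_identical(safe, naive)
  }
})

test_that("step_walk agrees with the exhaustive scorer on random volumes", {
  set.seed(1234)
  n_checked <- 0L
  for (rep in 1:20) {
    st <- random_blob_stack(20)
    cfg <- tracking_config(radius = sample(3:5, 1), cutoff = 0.35,
                           threshold = 0.5, backstep = sample(0:1, 1),
                           scalar = sample(0:2, 1), allowed_black = sample(0:1, 1),
                           bound_buffer = 2L, self_avoid = 3)
    safe <- boundary_safe_mask(st, cfg$bound_buffer)
    # start at the brightest voxel of a mid slice
    sl <- stack_slice(st, 10)
    w <- which(sl == max(sl), arr.ind = TRUE)[1, ]
    current <- c(w[2] - 1, w[1] - 1, 10)
    prev <- NULL
    claims_pkg <- myotrace:::new_claims(st, cfg$self_avoid)
    claims_orc <- myotrace:::new_claims(st, cfg$self_avoid)
    myotrace:::claim_path(claims_pkg, matrix(current, 1))
    myotrace:::claim_path(claims_orc, matrix(current, 1))
    for (step in 1:12) {
      got <- step_walk(st, current, prev, cfg, safe, direction = 1L,
                       claims = claims_pkg)
      want <- oracle_step(st, current, prev, cfg, safe, 1L, claims_orc)
      if (!is.null(want$stop)) {
        expect_equal(got$stop, want$stop)
        break
      }
      expect_equal(got$point, want$point)
      myotrace:::claim_path(claims_pkg, rasterize_segment(current, got$point))
      myotrace:::claim_path(claims_orc, rasterize_segment(current, want$point))
      current <- want$point
      prev <- want$direction
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 30)
})

test_that("the walk stops for the documented reasons", {
  # stack edge: at the last slice with a strictly forward cap
  a <- array(0.9, dim = c(6, 6, 4))
  st <- as_image_stack(a)
  cfg <- tracking_config(radius = 2, bound_buffer = 0L, cutoff = 0.5,
                         threshold = 0.5)
  safe <- boundary_safe_mask(st, 0L)
  out <- step_walk(st, c(3, 3, 3), NULL, cfg, safe, direction = 1L)
  expect_equal(out$stop, "stack_edge")

  # black fraction: isolated bright voxel in blackness
  b <- array(0, dim = c(11, 11, 11)); b[6, 6, 6] <- 0.9
  stb <- as_image_stack(b)
  cfgb <- tracking_config(radius = 3, cutoff = 0.5, threshold = 0.5,
                          allowed_black = 100L, bound_buffer = 0L)
  outb <- step_walk(stb, c(5, 5, 5), NULL, cfgb,
                    boundary_safe_mask(stb, 0L), direction = 1L)
  expect_equal(outb$stop, "black_fraction")

  # black paths: a thin black shell ahead that every path must cross, with
  # bright tissue beyond keeping the pooled black fraction low
  d <- array(0.9, dim = c(15, 15, 15)); d[, , 9] <- 0
  std <- as_image_stack(d)
  cfgd <- tracking_config(radius = 3, cutoff = 0.5, threshold = 0.5,
                          allowed_black = 0L, bound_buffer = 0L,
                          black_frac = 0.95)
  outd <- step_walk(std, c(7, 7, 7), NULL, cfgd,
                    boundary_safe_mask(std, 0L), direction = 1L)
  expect_equal(outd$stop, "black_paths")

  # boundary: all-bright volume, so the only boundary is the stack face
  e <- array(0.9, dim = c(9, 9, 9))
  ste <- as_image_stack(e)
  cfge <- tracking_config(radius = 2, cutoff = 0.5, threshold = 0.5,
                          bound_buffer = 4L)
  oute <- step_walk(ste, c(4, 4, 4), NULL, cfge,
                    boundary_safe_mask(ste, 4L), direction = 1L)
  expect_equal(oute$stop, "boundary")
})

test_that("track_fiber spans a straight tube and drops hopeless seeds", {
  ph <- small_phantom()
  st <- ph$stack
  cfg <- tracking_config(planes = 25L, seeds_per_plane = 4L, start_seed = 2L)
  cl1 <- subset(ph$truth$centerlines, fiber == 1)
  seed <- c(round(cl1$x[1]), round(cl1$y[1]), round(stats::median(cl1$z)))
  tr <- track_fiber(st, seed, cfg)
  expect_s3_class(tr, "fiber_track")
  zr <- range(tr$points[, 3])
  expect_lt(abs(zr[1] - min(cl1$z)), 4)
  expect_lt(abs(zr[2] - max(cl1$z)), 4)
  # all track points inside stack extents and on bright voxels
  expect_true(all(tr$points >= 0))
  expect_true(all(tr$gray >= cfg$cutoff))
  # seed in black space is dropped
  expect_null(track_fiber(st, c(1, 1, 1), cfg))
  # seed at the tube's end still yields a track (one walk direction is empty)
  end_seed <- c(round(cl1$x[1]), round(cl1$y[1]), round(min(cl1$z)) + 1)
  tr_end <- track_fiber(st, end_seed, cfg)
  expect_s3_class(tr_end, "fiber_track")
  expect_gt(diff(range(tr_end$points[, 3])), 20)
})

test_that("track_fibers is deterministic and respects the slice budget", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  save_stack(ph$stack, dir)
  st <- load_stack(dir)
  cfg <- tracking_config(planes = c(15L, 25L), seeds_per_plane = 4L,
                         start_seed = 5L)
  fs1 <- track_fibers(st, cfg)
  expect_lte(length(fs1$tracks), 8L)
  expect_gt(length(fs1$tracks), 0L)
  expect_lte(fs1$cache_peak, cfg$radius + cfg$backstep + 1L)
  st2 <- load_stack(dir)
  fs2 <- track_fibers(st2, cfg)
  expect_equal(lapply(fs1$tracks, `[[`, "points"),
               lapply(fs2$tracks, `[[`, "points"))
  # every fiber stays inside some tube's dilated mask
  sc <- score_against_truth(smooth_fibers(fs1, 1L), ph$truth, match_dist = 5,
                            contain_dist = ph$spec$tube_radius + 2)
  expect_equal(sc$n_outside, 0L)
  # blank stack yields an empty set
  blank <- make_stack(8, 8, 6, function(x, y, z) 0.1)
  w <- capture_warnings(fs0 <- track_fibers(blank, tracking_config(planes = 2L)))
  expect_match(w, "no ", all = FALSE)
  expect_equal(length(fs0$tracks), 0L)
})
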