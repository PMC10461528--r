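test_that("PNG stacks round-trip through save and load within quantization", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  save_stack(ph$stack, dir, bit_depth = 8L)
  st <- load_stack(dir)
  expect_s3_class(st, "image_stack")
  expect_equal(dim(st), dim(ph$stack))
  expect_equal(st$bit_depth, 8L)
  for (z in c(0L, st$n_slices %/% 2L, st$n_slices - 1L))
    expect_lt(max(abs(stack_slice(st, z) - stack_slice(ph$stack, z))),
              1 / 255 + 1e-12)
})

test_that("slice order follows natural filename sort and headers are checked", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.2, 4, 4), file.path(dir, "slice10.png"))
  png::writePNG(matrix(0.1, 4, 4), file.path(dir, "slice2.png"))
  writeLines("not an image", file.path(dir, "notes.txt"))
  expect_warning(st <- load_stack(dir), "non-PNG")
  expect_equal(st$n_slices, 2L)
  # slice2 must come before slice10
  expect_lt(mean(stack_slice(st, 0)), mean(stack_slice(st, 1)))
  png::writePNG(matrix(0.5, 3, 5), file.path(dir, "slice99.png"))
  expect_error(load_stack(dir), "mixed dimensions")
})

test_that("constant-value stacks load at the extremes of the gray range", {
  dir <- withr::local_tempdir()
  for (i in 1:3) png::writePNG(matrix(1, 4, 4), file.path(dir, sprintf("s%d.png", i)))
  expect_true(all(stack_slice(load_stack(dir), 1) == 1))
  dir2 <- withr::local_tempdir()
  for (i in 1:2) png::writePNG(matrix(0L, 4, 4) * 0, file.path(dir2, sprintf("s%d.png", i)))
  expect_true(all(stack_slice(load_stack(dir2), 0) == 0))
})

test_that("crop_stack finds the bounding box, pads it, and records offsets", {
  a <- array(0, dim = c(20, 20, 20))
  a[11, 11, 11] <- 0.9  # voxel (x=10, y=10, z=10)
  st <- as_image_stack(a)
  cr <- crop_stack(st, buffer = 2)
  expect_equal(dim(cr), c(5L, 5L, 5L))
  expect_equal(cr$offsets, c(8, 8, 8))
  expect_equal(stack_slice(cr, 2)[3, 3], 0.9)
  # realignment maps back exactly
  expect_equal(c(2, 2, 2) + cr$offsets, c(10, 10, 10))
  expect_error(crop_stack(as_image_stack(array(0, dim = c(4, 4, 4)))),
               "all-black")
})

test_that("crop_stack synthesizes black padding at touched faces", {
  a <- array(0, dim = c(10, 10, 10))
  a[1:4, 1:4, 1:4] <- 0.8  # content touches x=0, y=0, z=0
  cr <- crop_stack(as_image_stack(a), buffer = 2)
  expect_equal(cr$offsets, c(-2, -2, -2))
  expect_equal(dim(cr), c(8L, 8L, 8L))
  # buffer faces are black
  expect_true(all(stack_slice(cr, 0) == 0))
  expect_true(all(stack_slice(cr, 1) == 0))
  # content voxel (0,0,0) now sits at (2,2,2)
  expect_equal(stack_slice(cr, 2)[3, 3], 0.8)
  # content filling the whole volume still gains a buffer on all sides
  b <- array(0.5, dim = c(6, 6, 6))
  cr2 <- crop_stack(as_image_stack(b), buffer = 1)
  expect_equal(dim(cr2), c(8L, 8L, 8L))
  expect_equal(sum(stack_slice(cr2, 0) > 0), 0)
})

test_that("equalize_stack is a monotone min-max stretch to [0, 1]", {
  a <- array(0, dim = c(4, 4, 3))
  a[1, 1, 1] <- 0.25; a[2, 2, 2] <- 0.5
  eq <- equalize_stack(as_image_stack(a))
  expect_equal(stack_slice(eq, 0)[1, 1], 0.5)
  expect_equal(stack_slice(eq, 1)[2, 2], 1.0)
  vals <- c(sapply(0:2, function(z) stack_slice(eq, z)))
  expect_equal(range(vals), c(0, 1))
  # already-full-range stack unchanged
  b <- array(stats::runif(64), dim = c(4, 4, 4))
  b[1] <- 0; b[2] <- 1
  eq2 <- equalize_stack(as_image_stack(b))
  expect_equal(stack_slice(eq2, 0), stack_slice(as_image_stack(b), 0))
  expect_error(equalize_stack(as_image_stack(array(0.5, dim = c(3, 3, 3)))),
               "constant")
})

test_that("threshold masks use >= and are nested in the threshold", {
  st <- make_stack(6, 6, 3, function(x, y, z) 0.5)
  m <- threshold_preview(st, 1, c(0.5, 0.51, 0))
  expect_true(all(m[[1]]))
  expect_false(any(m[[2]]))
  expect_true(all(m[[3]]))
  ph <- small_phantom()
  mm <- threshold_preview(ph$stack, 20, c(0.3, 0.7))
  expect_true(all(mm[[2]] <= mm[[1]]))  # higher threshold is a subset
  path <- withr::local_tempfile(fileext = ".png")
  threshold_preview(ph$stack, 20, c(0.3, 0.7), path = path)
  expect_true(file.exists(path))
  expect_error(threshold_preview(ph$stack, 10^6, 0.5), "range")
})

test_that("the slice cache honors its limit and reports instrumentation", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  save_stack(ph$stack, dir)
  st <- load_stack(dir)
  stack_cache_limit(st, 3)
  for (z in 0:9) stack_slice(st, z)
  stats <- stack_cache_stats(st)
  expect_lte(stats$resident, 3)
  expect_lte(stats$peak, 3)
  expect_equal(stats$loads, 10L)
  stack_cache_reset(st)
  expect_equal(stack_cache_stats(st)$peak, 0L)
  # cached re-read returns identical pixels without a new decode
  a <- stack_slice(st, 4); loads <- stack_cache_stats(st)$loads
  b <- stack_slice(st, 4)
  expect_identical(a, b)
  expect_equal(stack_cache_stats(st)$loads, loads)
})
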