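test_that("height maps load and round-trip through text grids", {
  hm0 <- heightmap(matrix(0, 4, 4), 1)
  expect_equal(dim(hm0), c(4L, 4L))
  expect_true(all(hm0$heights == 0))

  set.seed(11)
  m <- matrix(rnorm(64 * 64), 64, 64)
  f <- withr::local_tempfile(fileext = ".csv")
  write_heightmap(heightmap(m, 0.8), f)
  hm <- load_heightmap(f, 0.8)
  expect_identical(hm$heights, m)
  expect_equal(hm$pixel_size_nm, 0.8)
})

test_that("malformed inputs are rejected", {
  expect_error(heightmap(array(0, c(3, 3, 3)), 1), "2D")
  expect_error(heightmap(matrix(c(1, NA, 1, 1), 2), 1), "finite")
  expect_error(heightmap(matrix(0, 3, 3), -1), "positive")
  # a 3D TIFF stack is a format error
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(8, 8, 3)), f)
  expect_error(load_heightmap(f, 1), "2D")
})

test_that("flatten removes planar and quadratic background exactly", {
  n <- 48
  x <- matrix(rep(seq_len(n), each = n), n) / n
  y <- matrix(rep(seq_len(n), times = n), n) / n
  plane <- 3 * x - 2 * y + 0.7
  hm <- heightmap(plane, 1)
  out <- flatten(hm, flatten_config(gaussian_px = 0))
  expect_lt(max(abs(out$heights)), 1e-6)
  quad <- plane + 1.5 * x^2 - 0.8 * y^2 + 0.5 * x * y
  out2 <- flatten(heightmap(quad, 1), flatten_config(gaussian_px = 0))
  expect_lt(max(abs(out2$heights)), 1e-6)
})

test_that("row offsets are aligned and the background is re-zeroed", {
  set.seed(3)
  n <- 48
  img <- matrix(0, n, n) + rep(rnorm(n), times = n) * 0  # start flat
  img <- img + matrix(rep(rnorm(n), times = n), n)       # per-row offsets
  out <- flatten(heightmap(img, 1), flatten_config(gaussian_px = 0))
  row_med <- apply(out$heights, 1, stats::median)
  expect_lt(max(abs(row_med)), 1e-6)
  expect_lt(abs(stats::median(out$heights)), 0.1)
})

test_that("flatten preserves ridge height above a tilted background", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  flat_ref <- flatten(fx$heightmap)
  h <- fx$heightmap$heights
  n1 <- nrow(h); n2 <- ncol(h)
  tilt <- 2 * outer(seq_len(n1) / n1, seq_len(n2) / n2, `+`)
  flat_tilt <- flatten(heightmap(h + tilt, 1))
  expect_lt(abs(max(flat_tilt$heights) - max(flat_ref$heights)) /
            max(flat_ref$heights), 0.05)
})

test_that("flatten correction steps are idempotent", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  cfg <- flatten_config(gaussian_px = 0)   # smoothing excluded: it composes
  once <- flatten(fx$heightmap, cfg)
  twice <- flatten(once, cfg)
  expect_lt(max(abs(twice$heights - once$heights)), 0.01)
})

test_that("flatten rejects tiny images", {
  expect_error(flatten(heightmap(matrix(0, 4, 4), 1)), "small")
})

test_that("mask_grains labels objects and applies area filters", {
  img <- matrix(0, 60, 60)
  img[cbind(px_circle(15, 15, 8)) + 1L] <- 2
  img[cbind(px_circle(45, 45, 8)) + 1L] <- 2
  hm <- heightmap(img, 1)
  mk <- mask_grains(hm, mask_config(threshold_nm = 0.5, min_area_px = 5))
  expect_equal(length(mk$counts), 2L)
  expect_lt(abs(diff(mk$counts)) / max(mk$counts), 0.1)
  # empty image
  mk0 <- mask_grains(heightmap(matrix(0, 20, 20), 1),
                     mask_config(threshold_nm = 0.5))
  expect_equal(length(mk0$counts), 0L)
})

test_that("sigma-relative threshold is invariant to a constant offset", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  flat <- flatten(fx$heightmap)
  cfg <- mask_config(threshold_sigma = 5, min_area_px = 30)
  m1 <- mask_grains(flat, cfg)
  m2 <- mask_grains(heightmap(flat$heights + 3.3, 1), cfg)
  expect_equal(length(m1$counts), length(m2$counts))
  expect_equal(m1$counts, m2$counts)
})

test_that("grain area is monotone non-increasing in the threshold", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  flat <- flatten(fx$heightmap)
  areas <- vapply(c(0.3, 0.6, 0.9, 1.2), function(thr) {
    mk <- mask_grains(flat, mask_config(threshold_nm = thr, min_area_px = 1))
    sum(mk$counts)
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("degenerate thresholds warn and empty the merged mask", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  flat <- flatten(fx$heightmap)
  w <- capture_warnings(mk <- mask_grains(flat, mask_config(threshold_nm = -0.5)))
  expect_true(any(grepl("degenerate", w)))
  expect_true(any(grepl("empty mask", w)))
  expect_equal(length(mk$counts), 0L)
})
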