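ridge_mask_hm <- function(width, height_fun, nrow = 40, len = 30) {
  # horizontal ridge of the given width; height_fun(offset) gives the height
  img <- matrix(0, nrow, nrow)
  r0 <- nrow %/% 2
  for (o in seq_len(width) - (width + 1L) %/% 2L) {
    img[r0 + o, 5:(5 + len)] <- height_fun(o)
  }
  hm <- heightmap(img, 1)
  mk <- mask_grains(hm, mask_config(threshold_nm = 0.1, min_area_px = 5))
  list(hm = hm, mask = mk, centre = r0 - 1L)
}

test_that("a symmetric ridge thins to its geometric centre line", {
  rf <- ridge_mask_hm(5, function(o) 2)
  sk <- skeletonize_height_biased(rf$mask, rf$hm, 1)
  inner <- sk[sk$col > 7 & sk$col < 32, ]
  expect_true(all(abs(inner$row - rf$centre) <= 0.5))
  deg <- skeleton_degree(sk)
  expect_equal(sum(deg == 1L), 2L)  # open line: two endpoints
})

test_that("height bias pulls the skeleton onto the height maximum", {
  # ridge whose maximum is offset one pixel from the geometric centre
  rf <- ridge_mask_hm(5, function(o) 2 + 0.5 * (o == 1L))
  sk <- skeletonize_height_biased(rf$mask, rf$hm, 1)
  inner <- sk[sk$col > 7 & sk$col < 32, ]
  frac_on_max <- mean(inner$row == rf$centre + 1L)
  expect_gte(frac_on_max, 0.9)
  # the unbiased skeleton stays on the geometric centre
  sk0 <- skeletonize_height_biased(rf$mask, rf$hm, 1, height_bias = FALSE)
  inner0 <- sk0[sk0$col > 7 & sk0$col < 32, ]
  expect_gte(mean(inner0$row == rf$centre), 0.5)
})

test_that("a solid disk collapses to a few pixels near the centroid", {
  img <- matrix(0, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    if ((r - 20)^2 + (c - 20)^2 <= 81) img[r, c] <- 2
  }
  hm <- heightmap(img, 1)
  mk <- mask_grains(hm, mask_config(threshold_nm = 0.1, min_area_px = 5))
  sk <- skeletonize_height_biased(mk, hm, 1)
  expect_lte(nrow(sk), 12L)
  expect_true(all(sqrt((sk$row - 19)^2 + (sk$col - 19)^2) < 6))
})

test_that("a closed ridge skeletonises to a single cycle of the right length", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  sks <- fixture_skeleton(fx)
  deg <- skeleton_degree(sks$sk)
  expect_true(all(deg == 2L))
  tr <- order_trace(sks$sk)
  expect_true(isTRUE(attr(tr$molecules[[1]], "closed")))
  len <- contour_length(tr$molecules[[1]], 1, closed = TRUE, smooth_px = 5L)
  expect_lt(abs(len - 400) / 400, 0.05)
})

test_that("height-biased skeletons sit at least as high as unbiased ones", {
  for (topo in c("torus_knot", "catenane_4node")) {
    sp <- synth_spec(topo, q = 3L, length_nm = 500, seed = 13)
    gt <- make_curve(sp)
    r <- render_pseudo_afm(gt, sp)
    flat <- flatten(r$heightmap)
    mk <- mask_grains(flat, mask_config(threshold_nm = 0.6, min_area_px = 60))
    skb <- skeletonize_height_biased(mk, flat, 1)
    sku <- skeletonize_height_biased(mk, flat, 1, height_bias = FALSE)
    expect_gte(mean(skb$height_nm), mean(sku$height_nm) - 1e-9)
  }
})

test_that("no 2x2 solid block survives skeletonisation", {
  fx <- fixture_render("torus_knot", q = 3L, seed = 5, length_nm = 600)
  sks <- fixture_skeleton(fx)
  m <- topotrace:::skeleton_matrix(sks$sk)
  blocks <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
    m[-nrow(m), -1] & m[-1, -1]
  expect_false(any(blocks))
})

test_that("empty grains are an error", {
  hm <- heightmap(matrix(0, 20, 20), 1)
  mk <- mask_grains(hm, mask_config(threshold_nm = 0.5))
  expect_error(skeletonize_height_biased(mk, hm, 1), "empty")
})
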