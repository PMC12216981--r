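test_that("exact generated curves carry verified topology labels", {
  expect_equal(make_curve(synth_spec("torus_knot", q = 3L,
                                     length_nm = 500))$rolfsen, "3_1")
  gt <- make_curve(synth_spec("torus_link", q = 4L, length_nm = 561))
  expect_equal(gt$rolfsen, "4^2_1")
  expect_equal(length(gt$curves), 2L)
  expect_equal(abs(linking_number(gt$curves[[1]], gt$curves[[2]])), 2,
               tolerance = 0.05)
  circ <- make_curve(synth_spec("circle", length_nm = 500))
  expect_equal(circ$rolfsen, "0_1")
  expect_equal(nrow(circ$crossings), 0L)
  expect_lt(abs(writhe_gauss(circ$curves[[1]])), 1e-9)
  expect_error(make_curve(synth_spec("torus_knot", p = 2L, q = 4L,
                                     length_nm = 500)), "coprime")
})

test_that("renders are deterministic in the seed", {
  sp <- synth_spec("torus_knot", q = 3L, length_nm = 500, noise_sd_nm = 0.1,
                   seed = 17L)
  r1 <- render_pseudo_afm(make_curve(sp), sp)
  r2 <- render_pseudo_afm(make_curve(sp), sp)
  expect_identical(r1$heightmap$heights, r2$heightmap$heights)
  sp2 <- synth_spec("torus_knot", q = 3L, length_nm = 500, noise_sd_nm = 0.1,
                    seed = 18L)
  r3 <- render_pseudo_afm(make_curve(sp2), sp2)
  expect_false(identical(r1$heightmap$heights, r3$heightmap$heights))
})

test_that("the fixture suite manifest is reproducible and covers all topologies", {
  m1 <- fixture_suite(1L, conditions = "clean")
  m2 <- fixture_suite(1L, conditions = "clean")
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_setequal(m1$topology, c("circle", "torus_knot3", "twist_knot4",
                                 "torus_knot5", "twist_knot5",
                                 "catenane_4node"))
  expect_true(all(table(m1$topology) >= 1L))
})

test_that("rendered ridge width reflects the tip convolution", {
  fx <- fixture_render("circle", seed = 9, length_nm = 400)
  flat <- flatten(fx$heightmap)
  # horizontal profile through the circle centre crosses the ridge twice
  h <- flat$heights
  centre <- round(nrow(h) / 2)
  prof <- h[centre, ]
  s <- seq_along(prof) * flat$pixel_size_nm
  lobe <- prof
  lobe[seq_len(round(length(prof) / 2))] <- 0   # keep the right-hand crossing
  fw <- profile_fwhm(s, lobe)
  target <- 2 * fx$spec$tip_radius_nm + fx$spec$duplex_width_nm
  expect_lt(abs(fw - target) / target, 0.2)
})

test_that("clustered renders trigger the node merge rule", {
  sp <- topotrace:::suite_spec("catenane_4node", "clustered", 1L, 1L)
  gt <- make_curve(sp)
  r <- render_pseudo_afm(gt, sp)
  flat <- flatten(r$heightmap)
  mask <- mask_grains(flat, mask_config(threshold_nm = 0.6, min_area_px = 60))
  sk <- prune_skeleton(skeletonize_height_biased(mask, flat, 1))
  raw <- detect_nodes(sk)
  merged <- merge_close_nodes(raw, sk)
  expect_lt(length(merged), max(length(raw), 4L))
})

test_that("recovery is lost, not corrupted, when crossings are fully compressed", {
  sp0 <- synth_spec("catenane_4node", length_nm = 561, crossing_compression = 0,
                    seed = 5)
  r0 <- run_pipeline(render_pseudo_afm(make_curve(sp0), sp0)$heightmap,
                     pipeline_config())$results[1, ]
  expect_equal(r0$rolfsen, "4^2_1")
  sp1 <- synth_spec("catenane_4node", length_nm = 561, crossing_compression = 1,
                    seed = 5)
  r1 <- run_pipeline(render_pseudo_afm(make_curve(sp1), sp1)$heightmap,
                     pipeline_config())$results[1, ]
  expect_equal(r1$rolfsen, "unclassified")
  expect_match(r1$failure, "degenerate")
  expect_equal(r1$min_cor, 0)
})
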