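test_that("reference table entries verify against knot determinants", {
  tab <- knot_table()
  expect_true(all(c("3_1", "3_1*", "4_1", "5_1", "5_2", "7_2",
                    "2^2_1", "4^2_1") %in% names(tab)))
  # determinants were checked at build time; spot-check two here
  expect_equal(topotrace:::jones_determinant(tab[["5_2"]]$polys[[1]]), 7)
  expect_equal(topotrace:::jones_determinant(tab[["6_1"]]$polys[[1]]), 9)
})

test_that("exact curves classify to their Rolfsen labels", {
  expect_equal(classify_diagram(
    diagram_from_curves3d(topotrace:::torus_curves(2L, 3L, 1L)))$rolfsen, "3_1")
  expect_equal(classify_diagram(
    diagram_from_curves3d(topotrace:::torus_curves(2L, 5L, 1L)))$rolfsen, "5_1")
  expect_equal(classify_diagram(
    diagram_from_curves3d(topotrace:::twist_knot_curve(5L)))$family, "5_2")
  expect_equal(classify_diagram(
    diagram_from_curves3d(topotrace:::torus_curves(2L, 4L, 2L)))$family, "4^2_1")
  mir <- classify_diagram(mirror_diagram(
    diagram_from_curves3d(topotrace:::torus_curves(2L, 3L, 1L))))
  expect_equal(mir$rolfsen, "3_1*")
  expect_equal(mir$family, "3_1")
})

test_that("single and double crossing flips of the 4-node catenane degrade as expected", {
  d <- diagram_from_curves3d(topotrace:::torus_curves(2L, 4L, 2L))
  expect_equal(n_crossings(d), 4L)
  ids <- as.integer(names(d$signs))
  for (i in ids) {
    expect_equal(classify_diagram(flip_crossing(d, i))$family, "2^2_1")
  }
  for (j in seq_len(ncol(utils::combn(ids, 2L)))) {
    pr <- utils::combn(ids, 2L)[, j]
    dd <- flip_crossing(flip_crossing(d, pr[1]), pr[2])
    expect_equal(classify_diagram(dd)$rolfsen, "0^2_1")
  }
})

test_that("torus-knot diagrams with two flips never classify as twist knots", {
  d <- diagram_from_curves3d(topotrace:::torus_curves(2L, 5L, 1L))
  cb <- utils::combn(as.integer(names(d$signs)), 2L)
  for (j in seq_len(ncol(cb))) {
    dd <- flip_crossing(flip_crossing(d, cb[1, j]), cb[2, j])
    fam <- classify_diagram(dd)$family
    expect_true(fam %in% c("0_1", "3_1"))
  }
})

test_that("alternate label comes from inverting the least reliable crossing", {
  d <- diagram_from_curves3d(topotrace:::torus_curves(2L, 4L, 2L))
  cor <- stats::setNames(c(0.8, 0.7, 0.05, 0.6), names(d$signs))
  res <- classify_diagram(d, cor = cor)
  expect_equal(res$rolfsen, "4^2_1")
  expect_equal(res$min_cor, 0.05)
  expect_equal(res$alternate_rolfsen, "2^2_1")
})

test_that("tidy and glance methods expose the classification", {
  d <- diagram_from_curves3d(topotrace:::torus_curves(2L, 3L, 1L))
  res <- classify_diagram(d)
  td <- tidy(res)
  expect_equal(nrow(td), 3L)
  expect_true(all(td$sign == -1L))
  gl <- glance(res)
  expect_equal(gl$rolfsen, "3_1")
  expect_equal(gl$writhe, -3L)
})

test_that("classification probability reproduces the combinatorial model", {
  tre <- diagram_from_curves3d(topotrace:::torus_curves(2L, 3L, 1L))
  tab <- classification_probability(tre, p = 0.82)
  expect_equal(sum(tab$probability), 1, tolerance = 1e-12)
  expect_equal(tab$n_assignments[tab$topology == "0_1"], 6L)
  expect_equal(tab$n_assignments[tab$topology == "3_1"], 2L)
  expect_equal(tab$probability[tab$topology == "3_1"],
               0.82^3 + 0.18^3, tolerance = 1e-12)
  # certainty limit
  tab1 <- classification_probability(tre, p = 1)
  expect_equal(tab1$probability[tab1$topology == "3_1"], 1)
  # polynomial identity in p: total probability is 1 at several p values
  for (p in c(0.3, 0.6, 0.9)) {
    expect_equal(sum(classification_probability(tre, p)$probability), 1,
                 tolerance = 1e-12)
  }
  expect_error(classification_probability(tre, p = 0), "probability")
})
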