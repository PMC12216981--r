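test_that("bracket normalisation removes Reidemeister I kinks", {
  kink_pos <- knot_diagram(
    list(data.frame(crossing = c(1L, 1L), over = c(TRUE, FALSE))),
    c(`1` = 1L))
  kink_neg <- knot_diagram(
    list(data.frame(crossing = c(1L, 1L), over = c(FALSE, TRUE))),
    c(`1` = -1L))
  one <- topotrace:::lp_mono(1, 0L)
  expect_true(lp_eq(jones_polynomial(kink_pos), one))
  expect_true(lp_eq(jones_polynomial(kink_neg), one))
})

test_that("Jones polynomials match the published table values", {
  # left-handed trefoil: -t^-4 + t^-3 + t^-1
  tre <- diagram_from_curves3d(topotrace:::torus_curves(2L, 3L, 1L))
  v_tre <- jones_polynomial(tre)
  expect_true(lp_eq(v_tre, lp_from_t(c(`-4` = -1, `-3` = 1, `-1` = 1))))
  # figure-eight: t^2 - t + 1 - t^-1 + t^-2 (amphichiral)
  f8 <- simplify_diagram(diagram_from_curves3d(topotrace:::twist_knot_curve(4L)))
  v_f8 <- jones_polynomial(f8)
  expect_true(lp_eq(v_f8, lp_from_t(c(`2` = 1, `1` = -1, `0` = 1,
                                      `-1` = -1, `-2` = 1))))
  expect_true(lp_eq(v_f8, topotrace:::lp_mirror(v_f8)))
  # Hopf link: -t^(-1/2) - t^(-5/2) for this chirality
  hopf <- diagram_from_curves3d(topotrace:::torus_curves(2L, 2L, 2L))
  expect_true(lp_eq(jones_polynomial(hopf),
                    lp_from_t(c(`-0.5` = -1, `-2.5` = -1))))
  # unknot and 2-component unlink
  circ <- knot_diagram(list(data.frame(crossing = integer(), over = logical())),
                       integer(0))
  expect_true(lp_eq(jones_polynomial(circ), topotrace:::lp_mono(1, 0L)))
  unl <- knot_diagram(rep(list(data.frame(crossing = integer(), over = logical())), 2),
                      integer(0))
  expect_true(lp_eq(jones_polynomial(unl),
                    lp_from_t(c(`0.5` = -1, `-0.5` = -1))))
})

test_that("mirror image maps the polynomial by t -> 1/t", {
  for (q in c(3L, 5L)) {
    d <- diagram_from_curves3d(topotrace:::torus_curves(2L, q, 1L))
    expect_true(lp_eq(jones_polynomial(mirror_diagram(d)),
                      topotrace:::lp_mirror(jones_polynomial(d))))
  }
})

test_that("state sum equals the recursive skein oracle on random diagrams", {
  set.seed(42)
  tested <- 0L
  tries <- 0L
  while (tested < 8L && tries < 60L) {
    tries <- tries + 1L
    cv <- random_curve(amp = 1.1)
    d <- tryCatch(diagram_from_curves3d(cv), error = function(e) NULL)
    if (is.null(d) || n_crossings(d) > 6L) next
    expect_true(lp_eq(jones_polynomial(d), oracle_jones(d)),
                info = paste("random diagram with", n_crossings(d), "crossings"))
    tested <- tested + 1L
  }
  expect_gte(tested, 5L)
})

test_that("simplification preserves the Jones polynomial", {
  set.seed(7)
  tested <- 0L
  tries <- 0L
  while (tested < 6L && tries < 60L) {
    tries <- tries + 1L
    cv <- random_curve(harmonics = 4, amp = 1.1)
    d <- tryCatch(diagram_from_curves3d(cv), error = function(e) NULL)
    if (is.null(d) || n_crossings(d) > 6L || n_crossings(d) < 1L) next
    ds <- simplify_diagram(d)
    expect_lte(n_crossings(ds), n_crossings(d))
    expect_true(lp_eq(jones_polynomial(ds), jones_polynomial(d)))
    tested <- tested + 1L
  }
  expect_gte(tested, 4L)
})

test_that("Reidemeister I and II configurations reduce to the unknot", {
  kink <- knot_diagram(
    list(data.frame(crossing = c(1L, 1L), over = c(TRUE, FALSE))),
    c(`1` = 1L))
  expect_equal(n_crossings(simplify_diagram(kink)), 0L)
  # two cancelling crossings between two strands of one component
  r2 <- knot_diagram(
    list(data.frame(crossing = c(1L, 2L, 2L, 1L),
                    over = c(TRUE, TRUE, FALSE, FALSE))),
    c(`1` = 1L, `2` = -1L))
  expect_equal(n_crossings(simplify_diagram(r2)), 0L)
  # a minimal trefoil is already reduced
  tre <- diagram_from_curves3d(topotrace:::torus_curves(2L, 3L, 1L))
  expect_equal(n_crossings(simplify_diagram(tre)), 3L)
})

test_that("diagram refuses state sums beyond the crossing limit", {
  d <- diagram_from_curves3d(topotrace:::torus_curves(2L, 7L, 1L))
  expect_error(jones_polynomial(d, max_crossings = 5L), "state-sum limit")
})
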