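paired_nodes <- function(sk, flat, merge_dist_nm = 7) {
  nodes <- merge_close_nodes(detect_nodes(sk), sk, merge_dist_nm)
  lapply(nodes, function(nd) call_crossing_order(pair_branches(nd, sk), sk, flat))
}

test_that("a simple cycle orders into one closed molecule covering all pixels", {
  sk <- skeleton_from_coords(px_circle(25, 25, 15), dim = c(55, 55))
  tr <- order_trace(sk)
  expect_equal(length(tr$molecules), 1L)
  m <- tr$molecules[[1]]
  expect_true(isTRUE(attr(m, "closed")))
  expect_equal(nrow(m), nrow(sk))
  expect_equal(m$N, seq_len(nrow(m)) - 1L)
  # consecutive points are 8-adjacent
  expect_true(all(pmax(abs(diff(m$X)), abs(diff(m$Y))) <= 1.5))
})

test_that("entangled catenane molecules separate into two closed traces", {
  fx <- fixture_render("catenane_4node", seed = 3, length_nm = 561)
  sks <- fixture_skeleton(fx)
  nodes <- paired_nodes(sks$sk, sks$flat)
  tr <- order_trace(sks$sk, nodes)
  expect_equal(length(tr$molecules), 2L)
  expect_true(all(vapply(tr$molecules, function(m) isTRUE(attr(m, "closed")), TRUE)))
  # each molecule passes through all four shared crossing regions
  for (m in tr$molecules) {
    expect_equal(length(unique(m$Z[m$Z > 0])) + 0L, 2L)  # over on some, under on others
    expect_gte(sum(m$Z > 0), 4L)
  }
})

test_that("a trefoil traces as one molecule visiting each node twice", {
  fx <- fixture_render("torus_knot", q = 3L, seed = 5, length_nm = 600)
  sks <- fixture_skeleton(fx)
  nodes <- paired_nodes(sks$sk, sks$flat)
  tr <- order_trace(sks$sk, nodes)
  expect_equal(length(tr$molecules), 1L)
  m <- tr$molecules[[1]]
  expect_true(isTRUE(attr(m, "closed")))
  # six crossing-region passages (three nodes, each passed twice)
  runs <- rle(m$Z > 0)
  expect_equal(sum(runs$values), 6L)
})

test_that("every connecting-segment pixel appears in exactly one molecule", {
  fx <- fixture_render("catenane_4node", seed = 3, length_nm = 561)
  sks <- fixture_skeleton(fx)
  nodes <- paired_nodes(sks$sk, sks$flat)
  tr <- order_trace(sks$sk, nodes)
  nx <- to_nxyz(tr)
  node_px <- do.call(rbind, lapply(nodes, function(nd) nd$coords))
  seg <- dplyr::anti_join(
    tibble::tibble(row = sks$sk$row, col = sks$sk$col),
    tibble::tibble(row = node_px[, 1], col = node_px[, 2]),
    by = c("row", "col"))
  traced <- tibble::tibble(row = round(nx$Y), col = round(nx$X))
  hit <- dplyr::inner_join(seg, dplyr::distinct(traced), by = c("row", "col"))
  expect_equal(nrow(hit), nrow(seg))
  # and no segment pixel is traced twice
  dup <- dplyr::semi_join(traced[duplicated(traced), ], seg, by = c("row", "col"))
  expect_equal(nrow(dup), 0L)
})

test_that("NXYZ re-indexes every molecule from zero", {
  fx <- fixture_render("catenane_4node", seed = 3, length_nm = 561)
  sks <- fixture_skeleton(fx)
  nodes <- paired_nodes(sks$sk, sks$flat)
  nx <- to_nxyz(order_trace(sks$sk, nodes), object_id = 7L)
  expect_setequal(unique(nx$object_id), 7L)
  for (mid in unique(nx$molecule_id)) {
    n <- nx$N[nx$molecule_id == mid]
    expect_equal(n, seq_along(n) - 1L)
  }
  expect_true(all(nx$Z[nx$Z != 0] %in% c(1L, 2L)))
})

test_that("open molecules keep endpoints and zero pseudo-heights", {
  sk <- skeleton_from_coords(px_line(10, 5, 30, 30), dim = c(40, 40))
  tr <- order_trace(sk)
  m <- tr$molecules[[1]]
  expect_false(isTRUE(attr(m, "closed")))
  expect_true(all(m$Z == 0))
  expect_equal(end_to_end_distance(m, 1, closed = FALSE),
               sqrt(20^2 + 25^2), tolerance = 0.1)
})

test_that("closed-trace step sum equals the raw contour length", {
  sk <- skeleton_from_coords(px_circle(25, 25, 15), dim = c(55, 55))
  tr <- order_trace(sk)
  m <- tr$molecules[[1]]
  d <- sqrt(diff(c(m$X, m$X[1]))^2 + diff(c(m$Y, m$Y[1]))^2)
  expect_equal(contour_length(m, 1, closed = TRUE), sum(d), tolerance = 1e-9)
})

test_that("tracing through an unpaired junction raises a tracing error", {
  y <- unique(rbind(px_line(20, 5, 20, 20), px_line(20, 20, 8, 32),
                    px_line(20, 20, 32, 32)))
  sk <- skeleton_from_coords(y, dim = c(40, 40))
  nodes <- detect_nodes(sk)
  expect_error(order_trace(sk, nodes), class = "topotrace_tracing_error")
})
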