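#' Ground-truthed parametric DNA curves
#'
#' Generates closed 3D curves for the topologies the pseudo-AFM generator can
#' render: circles, theta structures (partially replicated circles),
#' figure-of-8 late replication intermediates, (2, q) torus knots, twist
#' knots, (2, 2k) torus links and the 4-node catenane.  The exact curve is
#' classified at generation time by projecting it to a crossing diagram, so
#' the returned ground truth carries a verified topology label.
#'
#' @param spec a [synth_spec()].
#' @return an object of class `ground_truth`: a list with elements `curves`
#'   (list of n x 3 matrices, nm), `closed`, `lengths_nm`, `crossings`
#'   (data frame of true crossing positions, over component and sign),
#'   `rolfsen`, `conformation` and the originating `spec`.
#' @examples
#' gt <- make_curve(synth_spec("torus_knot", p = 2, q = 3, length_nm = 400))
#' gt$rolfsen
#' @export
make_curve <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  topo <- spec$topology
  open_curves <- NULL
  curves <- switch(topo,
    circle = list(circle_xyz(1, n = 240)),
    theta = {
      th <- theta_xyz()
      open_curves <- th$open
      list(th$circle)
    },
    figure8_dimer = list(lemniscate_xyz()),
    torus_knot = torus_curves(spec$p, spec$q, 1L),
    torus_link = torus_curves(2L, spec$q, 2L),
    catenane_4node = torus_curves(2L, 4L, 2L),
    twist_knot = twist_knot_curve(spec$n_crossings_target),
    stop("unknown topology: ", topo)
  )
  if (isTRUE(spec$mirror)) {
    curves <- lapply(curves, function(m) { m[, 3] <- -m[, 3]; m })
    open_curves <- lapply(open_curves, function(m) { m[, 3] <- -m[, 3]; m })
  }
  # scale to the requested total contour length; the deposited molecule lies
  # in the surface plane, so the XY-projected length is the physical one
  # (the z component only encodes the crossing order)
  len1 <- sum(vapply(curves, function(m) polyline_length(m[, 1:2]), 0)) +
    sum(vapply(open_curves %||% list(), function(m)
      polyline_length(m[, 1:2], closed = FALSE), 0))
  sc <- spec$length_nm / len1
  curves <- lapply(curves, function(m) m * sc)
  open_curves <- lapply(open_curves %||% list(), function(m) m * sc)
  if (topo == "theta" && isTRUE(spec$fork_stub_nm > 0)) {
    # regressed-fork stub: a short fourth arm on the right-hand junction,
    # in nm so its length is independent of the molecule scale
    jx <- sc * 1
    xs <- seq(0, spec$fork_stub_nm, length.out = 12)
    open_curves <- c(open_curves, list(cbind(jx + xs, xs * 0.3, 0)))
  }
  lengths <- vapply(curves, function(m) polyline_length(m[, 1:2]), 0)
  open_lengths <- vapply(open_curves, function(m)
    polyline_length(m[, 1:2], closed = FALSE), 0)

  if (topo == "theta") {
    rolfsen <- "theta"
    crossings <- empty_crossings()
    conf <- "open"
  } else {
    d <- diagram_from_curves3d(curves)
    xy <- attr(d, "crossing_xy")
    crossings <- cbind(as.data.frame(xy), crossing_table(d))
    cls <- classify_diagram(simplify_diagram(d))
    rolfsen <- cls$rolfsen
    conf <- "open"
  }
  structure(list(curves = curves, open_curves = open_curves,
                 closed = rep(TRUE, length(curves)),
                 lengths_nm = lengths, open_lengths_nm = open_lengths,
                 crossings = crossings, rolfsen = rolfsen,
                 conformation = conf, spec = spec),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$spec$topology, ": ", length(x$curves),
      " closed curve(s), total length ",
      round(sum(x$lengths_nm) + sum(x$open_lengths_nm), 1), " nm, topology ",
      x$rolfsen, ", ", nrow(x$crossings), " crossing(s)\n", sep = "")
  invisible(x)
}

crossing_table <- function(d) {
  n <- n_crossings(d)
  if (n == 0L) {
    return(data.frame(crossing = integer(), sign = integer(),
                      over_comp = integer()))
  }
  over_comp <- integer(n)
  for (i in seq_along(d$components)) {
    co <- d$components[[i]]
    over_comp[co$crossing[co$over]] <- i
  }
  data.frame(crossing = seq_len(n), sign = as.integer(d$signs),
             over_comp = over_comp)
}

polyline_length <- function(m, closed = TRUE) {
  n <- nrow(m)
  idx <- if (closed) c(2:n, 1L) else 2:n
  base <- if (closed) seq_len(n) else seq_len(n - 1L)
  sum(sqrt(rowSums((m[idx, , drop = FALSE] - m[base, , drop = FALSE])^2)))
}

circle_xyz <- function(r, n = 240, z = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(r * cos(th), r * sin(th), z)
}

# theta structure: a replication bubble (two equal arcs) bounded by two
# 3-way junctions, with the unreplicated parent strand crossing between them
# as the shortest segment; a gentle bow keeps the chord off the arcs
theta_xyz <- function(n = 240) {
  circ <- circle_xyz(1, n)
  xs <- seq(-1, 1, length.out = 60)
  chord <- cbind(xs, 0.12 * (1 - xs^2), 0)
  list(circle = circ, open = list(chord))
}

# closed curve with a single trivial self-crossing (Gerono lemniscate)
lemniscate_xyz <- function(n = 280) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cos(t), sin(t) * cos(t), 0.12 * sin(t))
}

# (p, q) torus knot (one component) or (2, q) torus link (two components)
torus_curves <- function(p, q, n_comp, R = 1, r = 0.55, n = 360) {
  if (n_comp == 1L) {
    if (gcd2(p, q) != 1L) stop("torus knot requires coprime (p, q)")
    s <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    list(cbind((R + r * cos(q * s)) * cos(p * s),
               (R + r * cos(q * s)) * sin(p * s),
               r * sin(q * s)))
  } else {
    stopifnot(p == 2L, q %% 2L == 0L)
    k <- q / 2
    s <- seq(0, 2 * pi, length.out = n / 2 + 1L)[-(n / 2 + 1L)]
    lapply(c(0, pi), function(ph) {
      cbind((R + r * cos(k * s + ph)) * cos(s),
            (R + r * cos(k * s + ph)) * sin(s),
            r * sin(k * s + ph))
    })
  }
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

# twist knot with n crossings: (n - 2) half twists plus a clasp, realised as
# the 4-plat of the rational tangle [k, 1, 1] (the 2-bridge knot C(k, 2));
# knot determinants 2k + 1 are verified when the reference table is built
twist_knot_curve <- function(n_cross) {
  plat_closure_curve(twist_knot_word(n_cross))
}

twist_knot_word <- function(n_cross) {
  if (is.null(n_cross) || n_cross < 3L || n_cross > 7L) {
    stop("twist knots are supported for 3 to 7 crossings")
  }
  c(rep(2L, n_cross - 2L), -1L, 2L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
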