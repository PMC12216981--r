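#' Crossings of projected polylines
#'
#' Finds all transversal intersections between the XY projections of a set of
#' closed polylines (self-intersections and intersections between different
#' components).  Used both to build crossing diagrams from traced molecules
#' and to extract ground-truth crossings from synthetic 3D curves.
#'
#' @param comps list of numeric matrices with >= 2 columns (x, y, ...); each
#'   is a closed polyline (last vertex connects back to the first).
#' @return a data frame with one row per crossing: components, segment
#'   indices, segment parameters, arc positions and the intersection point.
#' @keywords internal
polyline_crossings <- function(comps) {
  segs <- list()
  for (ci in seq_along(comps)) {
    m <- comps[[ci]]
    n <- nrow(m)
    if (n < 3L) next
    nxt <- c(2:n, 1L)
    segs[[length(segs) + 1L]] <- data.frame(
      comp = ci, seg = seq_len(n),
      x0 = m[, 1], y0 = m[, 2],
      x1 = m[nxt, 1], y1 = m[nxt, 2]
    )
  }
  if (length(segs) == 0L) return(empty_crossings())
  S <- do.call(rbind, segs)
  S$dx <- S$x1 - S$x0
  S$dy <- S$y1 - S$y0
  len <- sqrt(S$dx^2 + S$dy^2)
  cell <- max(len, 1e-9)
  # spatial binning on segment bounding boxes to avoid the all-pairs test
  bx0 <- floor(pmin(S$x0, S$x1) / cell); bx1 <- floor(pmax(S$x0, S$x1) / cell)
  by0 <- floor(pmin(S$y0, S$y1) / cell); by1 <- floor(pmax(S$y0, S$y1) / cell)
  keys <- vector("list", nrow(S))
  for (i in seq_len(nrow(S))) {
    gx <- bx0[i]:bx1[i]; gy <- by0[i]:by1[i]
    keys[[i]] <- as.vector(outer(gx, gy, function(a, b) paste0(a, "_", b)))
  }
  bins <- split(rep(seq_len(nrow(S)), lengths(keys)), unlist(keys))
  cand <- unique(do.call(rbind, lapply(bins, function(ix) {
    if (length(ix) < 2L) return(NULL)
    t(utils::combn(sort(ix), 2L))
  })))
  if (is.null(cand) || nrow(cand) == 0L) return(empty_crossings())
  out <- list()
  ncomp_seg <- vapply(comps, nrow, 0L)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (S$comp[i] == S$comp[j]) {
      n <- ncomp_seg[S$comp[i]]
      d <- abs(S$seg[i] - S$seg[j])
      if (d <= 1L || d >= n - 1L) next  # same or adjacent segment
    }
    den <- S$dx[i] * S$dy[j] - S$dy[i] * S$dx[j]
    scl <- max(len[i] * len[j], 1e-12)
    if (abs(den) < 1e-9 * scl) next    # parallel / degenerate
    ex <- S$x0[j] - S$x0[i]; ey <- S$y0[j] - S$y0[i]
    ti <- (ex * S$dy[j] - ey * S$dx[j]) / den
    tj <- (ex * S$dy[i] - ey * S$dx[i]) / den
    if (ti < -1e-9 || ti >= 1 - 1e-9 || tj < -1e-9 || tj >= 1 - 1e-9) next
    out[[length(out) + 1L]] <- data.frame(
      comp_a = S$comp[i], seg_a = S$seg[i], t_a = ti, s_a = S$seg[i] + ti,
      comp_b = S$comp[j], seg_b = S$seg[j], t_b = tj, s_b = S$seg[j] + tj,
      x = S$x0[i] + ti * S$dx[i], y = S$y0[i] + ti * S$dy[i],
      tax = S$dx[i] / len[i], tay = S$dy[i] / len[i],
      tbx = S$dx[j] / len[j], tby = S$dy[j] / len[j]
    )
  }
  if (length(out) == 0L) return(empty_crossings())
  res <- do.call(rbind, out)
  # drop numerically duplicated hits (e.g. an intersection exactly at a vertex)
  key <- paste(res$comp_a, round(res$s_a, 6), res$comp_b, round(res$s_b, 6))
  res <- res[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_crossings <- function() {
  data.frame(comp_a = integer(), seg_a = integer(), t_a = numeric(),
             s_a = numeric(), comp_b = integer(), seg_b = integer(),
             t_b = numeric(), s_b = numeric(), x = numeric(), y = numeric(),
             tax = numeric(), tay = numeric(), tbx = numeric(), tby = numeric())
}

#' Build a crossing diagram from closed polylines with height information
#'
#' @param comps list of closed polylines; matrices with columns x, y, z.
#' @param z_at function(comp_index, seg_index, t) returning the strand height
#'   at a parameter position, used to decide which strand passes over.
#' @param z_tol minimum height separation to call the crossing order; closer
#'   strands raise an ambiguity error.
#' @return a `knot_diagram`; crossing positions are kept in attribute
#'   `crossing_xy`.
#' @keywords internal
diagram_from_polylines <- function(comps, z_at, z_tol = 1e-9) {
  cr <- polyline_crossings(comps)
  n <- nrow(cr)
  passages <- vector("list", length(comps))
  for (i in seq_along(comps)) passages[[i]] <- data.frame(s = numeric(), crossing = integer(), over = logical())
  signs <- integer(0)
  if (n > 0L) {
    for (k in seq_len(n)) {
      za <- z_at(cr$comp_a[k], cr$seg_a[k], cr$t_a[k])
      zb <- z_at(cr$comp_b[k], cr$seg_b[k], cr$t_b[k])
      if (abs(za - zb) <= z_tol) {
        stop("ambiguous crossing order at (", round(cr$x[k], 2), ", ",
             round(cr$y[k], 2), "): strand heights coincide")
      }
      a_over <- za > zb
      to <- if (a_over) c(cr$tax[k], cr$tay[k]) else c(cr$tbx[k], cr$tby[k])
      tu <- if (a_over) c(cr$tbx[k], cr$tby[k]) else c(cr$tax[k], cr$tay[k])
      signs[k] <- as.integer(sign(to[1] * tu[2] - to[2] * tu[1]))
      passages[[cr$comp_a[k]]] <- rbind(passages[[cr$comp_a[k]]],
        data.frame(s = cr$s_a[k], crossing = k, over = a_over))
      passages[[cr$comp_b[k]]] <- rbind(passages[[cr$comp_b[k]]],
        data.frame(s = cr$s_b[k], crossing = k, over = !a_over))
    }
  }
  comps_pass <- lapply(passages, function(p) {
    p <- p[order(p$s), c("crossing", "over"), drop = FALSE]
    rownames(p) <- NULL
    p
  })
  d <- knot_diagram(comps_pass, stats::setNames(signs, seq_len(n)))
  attr(d, "crossing_xy") <- if (n) cbind(x = cr$x, y = cr$y) else
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  d
}

#' Crossing diagram from 3D curves
#'
#' Projects closed 3D curves onto the XY plane and uses the true z
#' coordinates to assign the crossing order.
#'
#' @param curves list of closed polylines (n x 3 matrices), or a single matrix.
#' @return a `knot_diagram`.
#' @export
diagram_from_curves3d <- function(curves) {
  if (is.matrix(curves)) curves <- list(curves)
  diagram_from_polylines(curves, function(ci, si, t) {
    m <- curves[[ci]]
    n <- nrow(m)
    j2 <- if (si == n) 1L else si + 1L
    (1 - t) * m[si, 3] + t * m[j2, 3]
  })
}

#' Crossing diagram from an NXYZ trace table
#'
#' Converts an ordered molecule trace (columns `molecule_id`, `N`, `X`, `Y`,
#' `Z`, as produced by [to_nxyz()]) into a planar crossing diagram.  The XY
#' path of each closed molecule is the diagram projection; at each
#' self-intersection the strand with the larger pseudo-height `Z` (the
#' ascending integer rank assigned from the FWHM crossing-order call) passes
#' over.  Strands meeting with equal pseudo-height cannot be ordered and
#' raise an error, mirroring the clustered/degenerate crossing route of the
#' data-cleanup rules.
#'
#' @param nxyz a data frame with columns `molecule_id`, `N`, `X`, `Y`, `Z`
#'   (one object).  Open molecules (attribute or `closed` column set to
#'   `FALSE`) are rejected.
#' @return a `knot_diagram`.
#' @export
diagram_from_nxyz <- function(nxyz) {
  nxyz <- as.data.frame(nxyz)
  stopifnot(all(c("molecule_id", "N", "X", "Y", "Z") %in% names(nxyz)))
  if ("closed" %in% names(nxyz) && !all(nxyz$closed)) {
    stop("open (linear) molecules cannot be classified topologically")
  }
  mols <- split(nxyz[order(nxyz$molecule_id, nxyz$N), ], nxyz$molecule_id)
  comps <- lapply(mols, function(m) cbind(m$X, m$Y, m$Z))
  diagram_from_polylines(comps, function(ci, si, t) {
    m <- comps[[ci]]
    n <- nrow(m)
    j2 <- if (si == n) 1L else si + 1L
    max(m[si, 3], m[j2, 3])  # pseudo-heights are per-node integer ranks
  }, z_tol = 0.5)
}
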