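#' Writhe of a closed 3D curve by the discrete Gauss integral
#'
#' Computes the writhe as the double sum over non-adjacent segment pairs of
#' the exact Gauss-map solid angle of each pair (Klenin–Langowski method),
#' so integer quantisation of linking numbers holds even at coarse
#' discretisation.  Positive and negative values correspond to right- and
#' left-handed crossings.
#'
#' @param curve closed polyline, n x 3 matrix (first vertex not repeated).
#' @return writhe (dimensionless).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' writhe_gauss(cbind(cos(th), sin(th), 0))  # planar circle: 0
#' @export
writhe_gauss <- function(curve) {
  curve <- as.matrix(curve)
  stopifnot(ncol(curve) == 3, nrow(curve) >= 4)
  n <- nrow(curve)
  p2 <- curve[c(2:n, 1L), , drop = FALSE]
  total <- 0
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # segment n is adjacent to segment 1
    if (length(js) == 0L) next
    total <- total + sum(segment_pair_omega(curve[i, ], p2[i, ],
                                            curve[js, , drop = FALSE],
                                            p2[js, , drop = FALSE]))
  }
  total / (2 * pi)
}

#' Linking number of two closed curves by the discrete Gauss integral
#'
#' @param curve_a,curve_b closed polylines (n x 3 matrices), disjoint.
#' @return the Gauss linking integral; for disjoint closed curves this is an
#'   integer up to discretisation error.
#' @export
linking_number <- function(curve_a, curve_b) {
  curve_a <- as.matrix(curve_a); curve_b <- as.matrix(curve_b)
  stopifnot(ncol(curve_a) == 3, ncol(curve_b) == 3,
            nrow(curve_a) >= 3, nrow(curve_b) >= 3)
  na <- nrow(curve_a); nb <- nrow(curve_b)
  a2 <- curve_a[c(2:na, 1L), , drop = FALSE]
  b2 <- curve_b[c(2:nb, 1L), , drop = FALSE]
  total <- 0
  for (i in seq_len(na)) {
    total <- total + sum(segment_pair_omega(curve_a[i, ], a2[i, ],
                                            curve_b, b2))
  }
  total / (4 * pi)
}

#' Twist of a ribbon by frame rotation
#'
#' Integrates the angular rotation of the ribbon vector (edge minus axis)
#' about the axis tangent, using parallel transport between consecutive
#' segments.  For a closed ribbon, White's theorem gives
#' `Lk = Tw + Wr` linking this to [linking_number()] and [writhe_gauss()].
#'
#' @param axis closed polyline (n x 3), the ribbon axis.
#' @param edge closed polyline (n x 3), the ribbon edge, vertex-matched to
#'   `axis`.
#' @return twist in turns.
#' @export
twist_ribbon <- function(axis, edge) {
  axis <- as.matrix(axis); edge <- as.matrix(edge)
  stopifnot(all(dim(axis) == dim(edge)), ncol(axis) == 3)
  n <- nrow(axis)
  nxt <- c(2:n, 1L)
  tg <- axis[nxt, ] - axis
  tg <- tg / sqrt(rowSums(tg^2))
  u <- edge - axis
  u <- u - tg * rowSums(u * tg)
  nu <- sqrt(rowSums(u^2))
  if (any(nu < 1e-12)) stop("ribbon edge touches the axis")
  u <- u / nu
  total <- 0
  for (i in seq_len(n)) {
    j <- nxt[i]
    ut <- rotate_onto(u[i, ], tg[i, ], tg[j, ])
    ut <- ut - tg[j, ] * sum(ut * tg[j, ])
    ut <- ut / sqrt(sum(ut^2))
    s <- sum(cross3(ut, u[j, ]) * tg[j, ])
    c <- sum(ut * u[j, ])
    total <- total + atan2(s, c)
  }
  total / (2 * pi)
}

# minimal rotation taking tangent a onto tangent b, applied to v
rotate_onto <- function(v, a, b) {
  ax <- cross3(a, b)
  s <- sqrt(sum(ax^2))
  c <- sum(a * b)
  if (s < 1e-12) return(if (c > 0) v else -v)
  ax <- ax / s
  v * c + cross3(ax, v) * s + ax * sum(ax * v) * (1 - c)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Exact solid angle of the Gauss map over one segment against many segments.
# p1, p2: one segment (length-3 vectors); Q1, Q2: m x 3 matrices.
segment_pair_omega <- function(p1, p2, Q1, Q2) {
  m <- nrow(Q1)
  r13 <- sweep(Q1, 2, p1)        # q1 - p1
  r14 <- sweep(Q2, 2, p1)        # q2 - p1
  r23 <- sweep(Q1, 2, p2)        # q1 - p2
  r24 <- sweep(Q2, 2, p2)        # q2 - p2
  n1 <- rowcross(r13, r14)
  n2 <- rowcross(r14, r24)
  n3 <- rowcross(r24, r23)
  n4 <- rowcross(r23, r13)
  l1 <- sqrt(rowSums(n1^2)); l2 <- sqrt(rowSums(n2^2))
  l3 <- sqrt(rowSums(n3^2)); l4 <- sqrt(rowSums(n4^2))
  bad <- l1 < 1e-12 | l2 < 1e-12 | l3 < 1e-12 | l4 < 1e-12
  l1[l1 < 1e-12] <- 1; l2[l2 < 1e-12] <- 1
  l3[l3 < 1e-12] <- 1; l4[l4 < 1e-12] <- 1
  n1 <- n1 / l1; n2 <- n2 / l2; n3 <- n3 / l3; n4 <- n4 / l4
  clamp <- function(x) pmin(1, pmax(-1, x))
  om <- asin(clamp(rowSums(n1 * n2))) + asin(clamp(rowSums(n2 * n3))) +
        asin(clamp(rowSums(n3 * n4))) + asin(clamp(rowSums(n4 * n1)))
  r12 <- matrix(p2 - p1, m, 3, byrow = TRUE)
  r34 <- Q2 - Q1
  sg <- sign(rowSums(rowcross(r34, r12) * r13))
  dmin <- pmin(rowSums(r13^2), rowSums(r14^2), rowSums(r23^2), rowSums(r24^2))
  if (any(dmin < 1e-18)) stop("curves touch or intersect: Gauss integral undefined")
  om <- om * sg
  om[bad] <- 0
  om
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
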