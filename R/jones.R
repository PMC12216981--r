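#' Jones polynomial via the Kauffman bracket state sum
#'
#' Evaluates the Kauffman bracket by exhaustive expansion over all `2^n`
#' smoothings of the diagram's crossings, counting the resulting closed loops,
#' and normalises by the writhe: `V = (-A)^(-3w) <D>` with the Jones variable
#' `t = A^(-4)`.  The result is returned as a Laurent polynomial in `A`
#' (integer exponents even for links, where `t`-exponents are half-integers).
#' The state sum is exact but exponential, so diagrams are refused above
#' `max_crossings`; simplify first with [simplify_diagram()].
#'
#' @param diag a `knot_diagram`.
#' @param max_crossings refuse diagrams with more crossings than this
#'   (default 14).
#' @return a `laurent` polynomial in the bracket variable `A`.
#' @examples
#' circ <- knot_diagram(list(data.frame(crossing = integer(), over = logical())),
#'                      integer(0))
#' format(jones_polynomial(circ))  # "1"
#' @export
jones_polynomial <- function(diag, max_crossings = 14L) {
  n <- n_crossings(diag)
  if (n > max_crossings) {
    stop("diagram has ", n, " crossings; state-sum limit is ", max_crossings)
  }
  br <- kauffman_bracket(diag)
  w <- diagram_writhe(diag)
  lp_mul(lp_mono((-1)^abs(w), -3L * w), br)
}

#' Kauffman bracket of a diagram (unnormalised)
#' @keywords internal
kauffman_bracket <- function(diag) {
  pd <- pd_code(diag)
  n <- nrow(pd)
  n_arcs <- attr(pd, "n_arcs")
  nf <- attr(pd, "n_free_loops")
  delta <- laurent(c(-1, 0, 0, 0, -1), -2L)  # -A^-2 - A^2
  if (n == 0L) {
    loops <- n_components(diag)  # all components are free loops here
    if (loops == 0L) return(lp_mono(1, 0L))
    return(lp_pow(delta, loops - 1L))
  }
  total <- laurent()
  for (state in 0:(2^n - 1L)) {
    parent <- seq_len(n_arcs)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    a_cnt <- 0L
    for (i in seq_len(n)) {
      e <- pd[i, ]
      if (bitwAnd(state, bitwShiftL(1L, i - 1L)) == 0L) {
        a_cnt <- a_cnt + 1L
        joins <- list(c(e[1], e[2]), c(e[3], e[4]))
      } else {
        joins <- list(c(e[1], e[4]), c(e[2], e[3]))
      }
      for (jn in joins) {
        ra <- find(jn[1]); rb <- find(jn[2])
        if (ra != rb) parent[ra] <- rb
      }
    }
    roots <- vapply(seq_len(n_arcs), find, 0L)
    loops <- length(unique(roots)) + nf
    contrib <- lp_mul(lp_mono(1, 2L * a_cnt - n), lp_pow(delta, loops - 1L))
    total <- lp_add(total, contrib)
  }
  total
}

#' Jones polynomials over all component orientation choices
#'
#' The Kauffman bracket does not depend on orientation, but the writhe
#' normalisation does (inter-component crossing signs flip when one component
#' is reversed).  For classification of catenanes, where strand direction is
#' unknowable from an AFM image, every orientation variant is a legitimate
#' polynomial for the molecule.
#' @keywords internal
jones_all_orientations <- function(diag, max_crossings = 14L) {
  n <- n_crossings(diag)
  if (n > max_crossings) {
    stop("diagram has ", n, " crossings; state-sum limit is ", max_crossings)
  }
  br <- kauffman_bracket(diag)
  ws <- unique(vapply(orientation_variants(diag), diagram_writhe, 0))
  lapply(ws, function(w) lp_mul(lp_mono((-1)^abs(w), -3L * as.integer(w)), br))
}

#' Knot determinant |V(-1)| from a Jones polynomial in A
#' @keywords internal
jones_determinant <- function(v) {
  # t = -1 corresponds to A = exp(i pi / 4): evaluate on the complex unit circle
  a <- complex(modulus = 1, argument = pi / 4)
  round(abs(sum(v$coef * a^(v$lo + seq_along(v$coef) - 1L))), 6)
}
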