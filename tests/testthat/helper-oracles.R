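# Independent Kauffman bracket oracle: recursive skein expansion over the PD
# code, resolving one crossing at a time and counting the loops of each
# fully-smoothed state through explicit arc-identification lists.  Shares no
# code with the package's state-sum engine.

oracle_delta <- topotrace:::laurent(c(-1, 0, 0, 0, -1), -2L)

oracle_bracket <- function(diag) {
  pd <- pd_code(diag)
  nfree <- attr(pd, "n_free_loops")
  narcs <- attr(pd, "n_arcs")
  expand <- function(rows, joins, coef_exp) {
    if (nrow(rows) == 0L) {
      # count loops among arcs under the accumulated identifications
      parent <- seq_len(narcs)
      root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (j in joins) {
        ra <- root(j[1]); rb <- root(j[2])
        if (ra != rb) parent[ra] <- rb
      }
      loops <- length(unique(vapply(seq_len(narcs), root, 0L))) + nfree
      return(topotrace:::lp_mul(topotrace:::lp_mono(1, coef_exp),
                                topotrace:::lp_pow(oracle_delta, loops - 1L)))
    }
    e <- rows[1, ]
    rest <- rows[-1, , drop = FALSE]
    a <- expand(rest, c(joins, list(c(e[1], e[2]), c(e[3], e[4]))),
                coef_exp + 1L)
    b <- expand(rest, c(joins, list(c(e[1], e[4]), c(e[2], e[3]))),
                coef_exp - 1L)
    topotrace:::lp_add(a, b)
  }
  if (nrow(pd) == 0L) {
    loops <- n_components(diag)
    if (loops == 0L) return(topotrace:::lp_mono(1, 0L))
    return(topotrace:::lp_pow(oracle_delta, loops - 1L))
  }
  expand(pd, list(), 0L)
}

oracle_jones <- function(diag) {
  w <- diagram_writhe(diag)
  topotrace:::lp_mul(topotrace:::lp_mono((-1)^abs(w), -3L * as.integer(w)),
                     oracle_bracket(diag))
}

# Laurent polynomial from (exponent in t) -> coefficient pairs, converted to
# the bracket variable A via t = A^-4
lp_from_t <- function(coefs) {
  out <- topotrace:::laurent()
  for (i in seq_along(coefs)) {
    e <- as.numeric(names(coefs)[i])
    out <- topotrace:::lp_add(out, topotrace:::lp_mono(coefs[[i]], -4L * e))
  }
  out
}

lp_eq <- topotrace:::lp_equal

# random closed 3D curves (Fourier ring with harmonics) for property tests
random_curve <- function(n = 200, harmonics = 3, amp = 0.45) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- rep(1, n); z <- rep(0, n)
  for (k in 2:(harmonics + 1L)) {
    r <- r + amp / k * cos(k * th + stats::runif(1, 0, 2 * pi))
    z <- z + amp / k * sin(k * th + stats::runif(1, 0, 2 * pi))
  }
  cbind(r * cos(th), r * sin(th), z)
}
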