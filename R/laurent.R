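#' Laurent polynomials in the Kauffman bracket variable
#'
#' Knot invariants computed by the Kauffman bracket live in the ring of Laurent
#' polynomials in the bracket variable `A`; the Jones polynomial is obtained by
#' the substitution `t = A^-4`, which for links with an even number of
#' components produces half-integer powers of `t`.  Working in `A` keeps every
#' exponent an integer.  A `laurent` object stores a coefficient vector and the
#' exponent of its first coefficient.
#'
#' @param coef numeric coefficient vector, ascending powers.
#' @param lo integer exponent of `coef[1]`.
#' @return a `laurent` object.
#' @keywords internal
laurent <- function(coef = numeric(0), lo = 0L) {
  structure(list(coef = as.numeric(coef), lo = as.integer(lo)),
            class = "laurent")
}

lp_trim <- function(p) {
  nz <- which(abs(p$coef) > 1e-9)
  if (length(nz) == 0L) return(laurent())
  laurent(p$coef[nz[1]:nz[length(nz)]], p$lo + nz[1] - 1L)
}

lp_zero <- function(p) length(lp_trim(p)$coef) == 0L

#' @keywords internal
lp_mono <- function(c = 1, e = 0L) laurent(c, e)

lp_add <- function(p, q) {
  if (length(p$coef) == 0L) return(q)
  if (length(q$coef) == 0L) return(p)
  lo <- min(p$lo, q$lo)
  hi <- max(p$lo + length(p$coef), q$lo + length(q$coef)) - 1L
  out <- numeric(hi - lo + 1L)
  ip <- (p$lo - lo + 1L):(p$lo - lo + length(p$coef))
  iq <- (q$lo - lo + 1L):(q$lo - lo + length(q$coef))
  out[ip] <- out[ip] + p$coef
  out[iq] <- out[iq] + q$coef
  lp_trim(laurent(out, lo))
}

lp_mul <- function(p, q) {
  if (length(p$coef) == 0L || length(q$coef) == 0L) return(laurent())
  co <- numeric(length(p$coef) + length(q$coef) - 1L)
  for (i in seq_along(p$coef)) {
    idx <- i:(i + length(q$coef) - 1L)
    co[idx] <- co[idx] + p$coef[i] * q$coef
  }
  lp_trim(laurent(co, p$lo + q$lo))
}

lp_pow <- function(p, n) {
  out <- lp_mono(1, 0L)
  for (i in seq_len(n)) out <- lp_mul(out, p)
  out
}

#' Substitute A -> A^-1 (mirror image of the underlying diagram).
#' @keywords internal
lp_mirror <- function(p) {
  if (length(p$coef) == 0L) return(p)
  hi <- p$lo + length(p$coef) - 1L
  laurent(rev(p$coef), -hi)
}

lp_equal <- function(p, q) {
  p <- lp_trim(p); q <- lp_trim(q)
  length(p$coef) == length(q$coef) && p$lo == q$lo &&
    all(abs(p$coef - q$coef) < 1e-6)
}

lp_eval <- function(p, x) {
  if (length(p$coef) == 0L) return(0)
  sum(p$coef * x^(p$lo + seq_along(p$coef) - 1L))
}

#' Exponent span of a Laurent polynomial in the Jones variable t = A^-4.
#' For an alternating knot this equals the minimal crossing number.
#' @keywords internal
lp_t_span <- function(p) {
  p <- lp_trim(p)
  if (length(p$coef) <= 1L) return(0)
  (length(p$coef) - 1L) / 4
}

#' Render in the Jones variable t = A^-4 when exponents allow, else in A.
#' @export
format.laurent <- function(x, ...) {
  p <- lp_trim(x)
  if (length(p$coef) == 0L) return("0")
  exps <- p$lo + seq_along(p$coef) - 1L
  nz <- abs(p$coef) > 1e-9
  exps <- exps[nz]; co <- p$coef[nz]
  in_t <- all(exps %% 4 == 0)
  half_t <- all(exps %% 2 == 0)
  term <- function(c, e) {
    if (in_t || half_t) {
      te <- -e / 4
      v <- if (abs(te) < 1e-12) "" else if (abs(te - 1) < 1e-12) "t"
      else paste0("t^", if (te == round(te)) te else sprintf("(%g/2)", 2 * te))
    } else {
      v <- if (e == 0) "" else if (e == 1) "A" else paste0("A^", e)
    }
    cs <- if (v == "") as.character(c) else if (c == 1) v
    else if (c == -1) paste0("-", v) else paste0(c, v)
    cs
  }
  # order by descending t-power (ascending A-power) for t display
  s <- vapply(seq_along(co), function(i) term(co[i], exps[i]), "")
  out <- paste(s, collapse = " + ")
  gsub("\\+ -", "- ", out)
}

#' @export
print.laurent <- function(x, ...) {
  cat("<laurent> ", format(x), "\n", sep = "")
  invisible(x)
}
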