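#' Combinatorial crossing-misclassification model
#'
#' Given a diagram and a per-crossing probability `p` of calling the crossing
#' order correctly, enumerates every subset of crossings that could be
#' inverted, classifies each resulting diagram, and accumulates the
#' probability `p^(n-k) (1-p)^k` of each outcome topology (k = number of
#' inverted crossings).  With the hand-label benchmark accuracy `p = 0.82`
#' this reproduces the chance of recovering the correct topology for knots of
#' increasing node number (e.g. a minimal trefoil diagram has 6 of its 8
#' crossing-order assignments classifying as an unknot and 2 as a 3-node
#' knot).
#'
#' @param diag a `knot_diagram`.
#' @param p probability in (0, 1] that a single crossing order is called
#'   correctly.
#' @param collapse_chirality sum probabilities over mirror forms (a "3-node
#'   knot" of either handedness is one outcome); default `TRUE`.
#' @return a tibble with columns `topology`, `n_assignments`, `probability`,
#'   sorted by decreasing probability.  Probabilities sum to 1.
#' @examples
#' d <- diagram_from_curves3d(torus_curves(2L, 3L, 1L))
#' classification_probability(d, p = 0.82)
#' @export
classification_probability <- function(diag, p, collapse_chirality = TRUE) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must be a single probability in (0, 1]")
  }
  n <- n_crossings(diag)
  if (n > 20L) stop("enumeration limited to 20 crossings")
  ids <- as.integer(names(diag$signs))
  out <- vector("list", 2^n)
  for (mask in 0:(2^n - 1L)) {
    d <- diag
    k <- 0L
    for (i in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L) {
        d <- flip_crossing(d, ids[i])
        k <- k + 1L
      }
    }
    cls <- classify_diagram(d)
    lab <- if (collapse_chirality) cls$family else cls$rolfsen
    out[[mask + 1L]] <- data.frame(topology = lab, k = k)
  }
  res <- do.call(rbind, out)
  res$probability <- p^(n - res$k) * (1 - p)^res$k
  agg <- stats::aggregate(cbind(probability = res$probability) ~ topology,
                          data = res, FUN = sum)
  cnt <- stats::aggregate(cbind(n_assignments = res$probability) ~ topology,
                          data = res, FUN = length)
  out <- merge(cnt, agg, by = "topology")
  out <- out[order(-out$probability), ]
  tibble::as_tibble(out)
}
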