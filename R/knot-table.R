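#' Reference table of Jones polynomials for classification
#'
#' Molecules are classified by looking their Jones polynomial up in a table
#' of reference values computed, at first use, from exact diagrams of the
#' torus and twist families that the recombination products of interest fall
#' in: torus knots 3_1, 5_1, 7_1; twist knots 4_1, 5_2, 6_1, 7_2; and the
#' (2, 2k) torus links 2^2_1 (Hopf link / 2-node catenane), 4^2_1 (4-node
#' catenane) and 6^2_1.  Both chiralities are tabulated; a trailing `*` marks
#' the mirror form, and the unstarred form is anchored to the variant whose
#' Jones polynomial lies in negative powers of t (the usual table
#' convention).  Because strand orientation cannot be read from an AFM
#' image, link entries include every component-orientation variant.
#'
#' @return a named list; each element has `polys` (list of `laurent`
#'   reference polynomials) and `family` (label without chirality star).
#' @export
knot_table <- function() {
  if (!is.null(.topotrace$knot_table)) return(.topotrace$knot_table)
  refs <- list(
    `3_1` = function() diagram_from_curves3d(torus_curves(2L, 3L, 1L)),
    `5_1` = function() diagram_from_curves3d(torus_curves(2L, 5L, 1L)),
    `7_1` = function() diagram_from_curves3d(torus_curves(2L, 7L, 1L)),
    `4_1` = function() diagram_from_curves3d(twist_knot_curve(4L)),
    `5_2` = function() diagram_from_curves3d(twist_knot_curve(5L)),
    `6_1` = function() diagram_from_curves3d(twist_knot_curve(6L)),
    `7_2` = function() diagram_from_curves3d(twist_knot_curve(7L)),
    `2^2_1` = function() diagram_from_curves3d(torus_curves(2L, 2L, 2L)),
    `4^2_1` = function() diagram_from_curves3d(torus_curves(2L, 4L, 2L)),
    `6^2_1` = function() diagram_from_curves3d(torus_curves(2L, 6L, 2L))
  )
  # expected knot/link determinants |V(-1)|, a build-time sanity gate
  dets <- c(`3_1` = 3, `5_1` = 5, `7_1` = 7, `4_1` = 5, `5_2` = 7,
            `6_1` = 9, `7_2` = 11, `2^2_1` = 2, `4^2_1` = 4, `6^2_1` = 6)
  tab <- list()
  for (lab in names(refs)) {
    d <- simplify_diagram(refs[[lab]]())
    polys <- jones_all_orientations(d)
    det <- jones_determinant(polys[[1]])
    if (abs(det - dets[[lab]]) > 1e-6) {
      stop("reference diagram for ", lab, " has determinant ", det,
           ", expected ", dets[[lab]])
    }
    mpolys <- lapply(polys, lp_mirror)
    amphi <- all(vapply(polys, function(p)
      any(vapply(mpolys, lp_equal, TRUE, p = p)), TRUE))
    if (amphi) {
      # for multi-component links the polynomial pools unknowable strand
      # orientations, so a coincident mirror means "cannot tell", not
      # genuine amphichirality
      chir <- if (n_components(d) > 1L) "ambiguous" else "amphichiral"
      tab[[lab]] <- list(polys = polys, family = lab, chirality = chir)
    } else {
      # unstarred form: Jones polynomial in negative powers of t (positive A)
      cen <- mean(polys[[1]]$lo + seq_along(polys[[1]]$coef) - 1L)
      if (cen >= 0) {
        tab[[lab]] <- list(polys = polys, family = lab, chirality = "chiral")
        tab[[paste0(lab, "*")]] <- list(polys = mpolys, family = lab,
                                        chirality = "chiral")
      } else {
        tab[[lab]] <- list(polys = mpolys, family = lab, chirality = "chiral")
        tab[[paste0(lab, "*")]] <- list(polys = polys, family = lab,
                                        chirality = "chiral")
      }
    }
  }
  .topotrace$knot_table <- tab
  tab
}

.topotrace <- new.env(parent = emptyenv())

#' Classify a crossing diagram in Rolfsen notation
#'
#' Simplifies the diagram, computes its Jones polynomial (over all component
#' orientation choices, since strand direction is unknowable from an AFM
#' topograph) and matches it against [knot_table()].  Diagrams that simplify
#' to zero crossings are the unknot `0_1` (one component) or the unlink
#' `0^k_1`.  Unmatched polynomials give `"unclassified"`.
#'
#' @param diag a `knot_diagram`.
#' @param cor optional numeric vector of per-crossing crossing-order
#'   reliabilities, named by crossing id; when given, the classification
#'   after inverting the least reliable crossing is reported as
#'   `alternate_rolfsen`.
#' @param max_crossings refuse state sums above this size.
#' @return an object of class `topology_result` with fields `rolfsen`,
#'   `family`, `chirality`, `polynomial`, `n_crossings` (after
#'   simplification), `signs`, `alternate_rolfsen`, `min_cor`, `cor`.
#' @export
classify_diagram <- function(diag, cor = NULL, max_crossings = 14L) {
  ds <- simplify_diagram(diag)
  n <- n_crossings(ds)
  k <- n_components(ds)
  if (n == 0L) {
    lab <- if (k <= 1L) "0_1" else paste0("0^", k, "_1")
    res <- list(rolfsen = lab, family = lab, chirality = "amphichiral",
                polynomial = jones_polynomial(ds), n_crossings = 0L,
                signs = integer(0))
  } else if (n > max_crossings) {
    res <- list(rolfsen = "unclassified", family = "unclassified",
                chirality = NA_character_, polynomial = NULL,
                n_crossings = n, signs = as.integer(ds$signs))
  } else {
    polys <- jones_all_orientations(ds, max_crossings = max_crossings)
    tab <- knot_table()
    lab <- "unclassified"; fam <- "unclassified"; chir <- NA_character_
    for (nm in names(tab)) {
      hit <- any(vapply(polys, function(p)
        any(vapply(tab[[nm]]$polys, lp_equal, TRUE, p = p)), TRUE))
      if (hit) {
        lab <- nm; fam <- tab[[nm]]$family; chir <- tab[[nm]]$chirality
        break
      }
    }
    if (lab == "unclassified" &&
        any(vapply(polys, function(p) lp_equal(p, unlink_poly(k)), TRUE))) {
      lab <- fam <- if (k <= 1L) "0_1" else paste0("0^", k, "_1")
      chir <- "amphichiral"
    }
    res <- list(rolfsen = lab, family = fam, chirality = chir,
                polynomial = polys[[1]], n_crossings = n,
                signs = as.integer(ds$signs))
  }
  res$alternate_rolfsen <- NA_character_
  res$min_cor <- NA_real_
  res$cor <- cor
  if (!is.null(cor) && length(cor) && n_crossings(diag) > 0L) {
    cor <- cor[names(cor) %in% names(diag$signs)]
    if (length(cor)) {
      res$min_cor <- min(cor)
      worst <- names(cor)[which.min(cor)]
      alt <- classify_diagram(flip_crossing(diag, as.integer(worst)),
                              cor = NULL, max_crossings = max_crossings)
      res$alternate_rolfsen <- alt$rolfsen
    }
  }
  structure(res, class = "topology_result")
}

unlink_poly <- function(k) {
  delta <- laurent(c(-1, 0, 0, 0, -1), -2L)
  lp_pow(delta, max(k - 1L, 0L))
}

#' @export
print.topology_result <- function(x, ...) {
  cat("<topology_result> ", x$rolfsen, sep = "")
  if (!is.na(x$min_cor)) {
    cat("  (alternate ", x$alternate_rolfsen, ", min COR ",
        round(x$min_cor, 3), ")", sep = "")
  }
  cat("\n  crossings after simplification: ", x$n_crossings, sep = "")
  if (length(x$signs)) {
    cat(", signs ", paste0(ifelse(x$signs > 0, "+", "-"), collapse = ""))
  }
  cat("\n")
  if (!is.null(x$polynomial)) {
    cat("  Jones polynomial: ", format(x$polynomial), "\n", sep = "")
  }
  invisible(x)
}
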