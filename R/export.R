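#' Export helpers for pipeline artefacts
#'
#' Everything the pipeline produces is an ordinary tibble or matrix, so
#' `write.csv()` works directly; these helpers fix the column layout of the
#' interchange formats.
#'
#' @param sk an `afm_skeleton`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_skeleton_csv <- function(sk, path) {
  df <- tibble::tibble(molecule_id = attr(sk, "grain"),
                       row = sk$row, col = sk$col,
                       height_nm = sk$height_nm,
                       degree = skeleton_degree(sk))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_skeleton_csv
#' @param nxyz an NXYZ table from [to_nxyz()].
#' @export
write_nxyz_csv <- function(nxyz, path) {
  utils::write.csv(as.data.frame(nxyz), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_skeleton_csv
#' @param nodes list of `crossing_node`s with crossing order called.
#' @export
write_nodes_csv <- function(nodes, path) {
  rows <- lapply(nodes, function(nd) {
    tibble::tibble(node_id = nd$id,
                   n_branches = nd$n_branches,
                   fwhm_nm = paste(round(nd$fwhm_nm %||% numeric(0), 3),
                                   collapse = ";"),
                   over_pair = nd$over_pair %||% NA_integer_,
                   cor = nd$cor,
                   degenerate = isTRUE(nd$degenerate))
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' Diagram codes as JSON
#'
#' Serialises the PD code, Gauss code and crossing signs of a diagram.
#'
#' @param diag a `knot_diagram`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @export
diagram_to_json <- function(diag, path = NULL) {
  pd <- pd_code(diag)
  obj <- list(
    n_crossings = n_crossings(diag),
    n_components = n_components(diag),
    signs = as.integer(diag$signs),
    pd = unname(apply(pd, 1L, function(r) as.integer(r), simplify = FALSE)),
    gauss = unname(gauss_code(diag))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Flat results table of a pipeline run
#'
#' Collapses list columns (per-molecule contour lengths) to
#' semicolon-separated strings so the table can be written as CSV.
#'
#' @param result a `pipeline_result`.
#' @return a tibble with only atomic columns.
#' @export
results_table <- function(result) {
  r <- result$results
  r$contour_lengths_nm <- vapply(r$contour_lengths_nm, function(v)
    paste(round(v, 2), collapse = ";"), "")
  r
}

#' Summary JSON of a pipeline run
#'
#' Per-sample means and standard deviations of the main morphometric
#' quantities, plus classification counts.
#'
#' @param result a `pipeline_result`.
#' @param path optional file.
#' @export
results_summary_json <- function(result, path = NULL) {
  r <- result$results
  obj <- list(
    n_objects = nrow(r),
    topology_counts = as.list(table(r$rolfsen)),
    contour_length_nm = list(mean = mean(r$contour_length_nm, na.rm = TRUE),
                             sd = stats::sd(r$contour_length_nm, na.rm = TRUE)),
    crossings = list(mean = mean(r$n_crossings, na.rm = TRUE)),
    min_cor = list(mean = mean(r$min_cor, na.rm = TRUE)),
    conformation_counts = as.list(table(r$conformation))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
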