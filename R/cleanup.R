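#' Data cleanup filters for pipeline outputs
#'
#' Applies the standard post-tracing cleanup steps to a results table,
#' selecting the step set by analysis mode:
#' \enumerate{
#'   \item drop records with an empty contour length (the tracing failed);
#'   \item drop objects containing linear (open) molecules — broken masks or
#'     skeletons;
#'   \item drop objects with more than two crossing segments at a single
#'     crossing (unresolvable clustered crossings);
#'   \item drop objects whose molecule count does not match the sample type
#'     (one for knots, two for catenanes).
#' }
#' Modes use: topology 1-3; contour_length 1-4; crossing_distributions
#' 1, 2, 4; conformation 1-3.
#'
#' @param records a data frame with columns `contour_length_nm`,
#'   `has_linear` (logical), `clustered` (logical: any node with > 2
#'   crossing segments), `n_molecules` (integer), and optionally
#'   `sample_type` (`"knot"`/`"catenane"`); [run_pipeline()] produces these.
#' @param mode one of `"topology"`, `"contour_length"`,
#'   `"crossing_distributions"`, `"conformation"`.
#' @param sample_type default sample type when the column is absent.
#' @return the retained records; per-step removal counts are in attribute
#'   `removal_counts` (see [cleanup_log()]).
#' @export
cleanup_filter <- function(records,
                           mode = c("topology", "contour_length",
                                    "crossing_distributions", "conformation"),
                           sample_type = NULL) {
  mode <- match.arg(mode)
  steps <- switch(mode,
    topology = 1:3,
    contour_length = 1:4,
    crossing_distributions = c(1L, 2L, 4L),
    conformation = 1:3
  )
  records <- tibble::as_tibble(records)
  if (!"sample_type" %in% names(records)) {
    records$sample_type <- sample_type %||% NA_character_
  }
  removed <- stats::setNames(integer(4), paste0("step", 1:4))
  for (s in steps) {
    drop <- switch(s,
      is.na(records$contour_length_nm),
      isTRUE_vec(records$has_linear),
      isTRUE_vec(records$clustered),
      {
        expect <- ifelse(records$sample_type == "catenane", 2L, 1L)
        !is.na(records$sample_type) & records$n_molecules != expect
      }
    )
    drop[is.na(drop)] <- FALSE
    removed[s] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  attr(records, "removal_counts") <- removed
  records
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Removal counts of a cleanup run
#' @param records output of [cleanup_filter()].
#' @return named integer vector of per-step removal counts.
#' @export
cleanup_log <- function(records) attr(records, "removal_counts")
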