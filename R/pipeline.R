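#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Defaults are the values
#' used throughout: 7 nm node merge distance (about twice the tip-convolved
#' DNA width), 20 nm crossing region (below the DNA persistence length),
#' crossing-order reliability threshold 0.263 (the optimum of correct
#' against incorrect calls on hand-labelled crossings), 15 % / 0.85 nm
#' branch pruning.
#'
#' @param flatten a [flatten_config()].
#' @param mask a [mask_config()].
#' @param prune_length_frac,prune_height_drop_nm branch pruning thresholds.
#' @param merge_dist_nm node merge distance (nm).
#' @param region_nm crossing region diameter (nm).
#' @param cor_threshold crossing-order reliability below which an object's
#'   topology is reported low-confidence.
#' @param conformation a [conformation_rules()].
#' @param max_crossings Jones state-sum limit.
#' @param sample_type `"knot"`, `"catenane"` or `NULL` (unknown).
#' @param segmenter function `(heightmap, mask_config) -> grain_mask` used to
#'   mask molecules; defaults to the classical thresholder [mask_grains()].
#'   A learned segmenter can be plugged in here without touching the rest of
#'   the pipeline.
#' @param already_flat skip flattening (synthetic input is near-flat).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(flatten = flatten_config(),
                            mask = mask_config(threshold_nm = 0.6,
                                               min_area_px = 60L),
                            prune_length_frac = 0.15,
                            prune_height_drop_nm = 0.85,
                            merge_dist_nm = 7,
                            region_nm = 20,
                            cor_threshold = 0.263,
                            conformation = conformation_rules(),
                            max_crossings = 14L,
                            sample_type = NULL,
                            segmenter = mask_grains,
                            length_smooth_px = 5L,
                            already_flat = FALSE) {
  structure(list(flatten = flatten, mask = mask,
                 prune_length_frac = prune_length_frac,
                 prune_height_drop_nm = prune_height_drop_nm,
                 merge_dist_nm = merge_dist_nm, region_nm = region_nm,
                 cor_threshold = cor_threshold, conformation = conformation,
                 max_crossings = max_crossings, sample_type = sample_type,
                 segmenter = segmenter,
                 length_smooth_px = as.integer(length_smooth_px),
                 already_flat = isTRUE(already_flat)),
            class = "pipeline_config")
}

#' Run the full tracing and classification pipeline
#'
#' For each input height map: flatten, mask, and for every grain
#' skeletonise (height-biased), prune, detect and merge crossing nodes,
#' pair branches, call the crossing order by FWHM, order the trace,
#' separate entangled molecules, classify the topology from the NXYZ
#' diagram, and collect morphometrics.  Unclassifiable molecules (junctions,
#' clustered crossings, inconsistent pairings) never abort the run — they
#' are reported with an `unclassified` topology and the failure reason.
#'
#' @param images a list of `afm_heightmap` objects (or file paths, loaded
#'   with `pixel_size_nm`).
#' @param config a [pipeline_config()].
#' @param pixel_size_nm used when `images` contains paths.
#' @return an object of class `pipeline_result`: `results` (a tibble, one
#'   row per object), `nxyz` (bound NXYZ table) and `config`.
#' @export
run_pipeline <- function(images, config = pipeline_config(),
                         pixel_size_nm = 1) {
  if (inherits(images, "afm_heightmap")) images <- list(images)
  rows <- list()
  nxyz_all <- list()
  for (ii in seq_along(images)) {
    hm <- images[[ii]]
    if (is.character(hm)) hm <- load_heightmap(hm, pixel_size_nm)
    flat <- if (config$already_flat) hm else flatten(hm, config$flatten)
    mask <- config$segmenter(flat, config$mask)
    for (gi in seq_along(mask$counts)) {
      res <- trace_object(flat, mask, gi, config)
      res$image <- ii
      rows[[length(rows) + 1L]] <- res$row
      if (!is.null(res$nxyz)) {
        res$nxyz$object_id <- paste0(ii, ":", gi)
        nxyz_all[[length(nxyz_all) + 1L]] <- res$nxyz
      }
    }
  }
  structure(list(results = dplyr::bind_rows(rows),
                 nxyz = dplyr::bind_rows(nxyz_all),
                 config = config),
            class = "pipeline_result")
}

trace_object <- function(flat, mask, gi, config) {
  ps <- flat$pixel_size_nm
  base_row <- tibble::tibble(
    object_id = NA_character_, grain = gi,
    rolfsen = "unclassified", alternate_rolfsen = NA_character_,
    n_crossings = NA_integer_, avg_cor = NA_real_, min_cor = NA_real_,
    n_molecules = NA_integer_, contour_length_nm = NA_real_,
    contour_lengths_nm = list(numeric(0)),
    has_linear = NA, clustered = NA, conformation = NA_character_,
    reliable = NA, failure = NA_character_
  )
  out <- base_row
  nxyz <- NULL
  tryCatch({
    sk <- skeletonize_height_biased(mask, flat, gi)
    sk <- prune_skeleton(sk, config$prune_length_frac,
                         config$prune_height_drop_nm)
    nodes <- detect_nodes(sk)
    nodes <- merge_close_nodes(nodes, sk, config$merge_dist_nm)
    out$conformation <- classify_conformation(nodes, ps, config$conformation)
    out$clustered <- any(vapply(nodes, function(nd) nd$n_branches > 4L, TRUE))
    paired <- TRUE
    for (i in seq_along(nodes)) {
      if (nodes[[i]]$n_branches >= 4L && nodes[[i]]$n_branches %% 2L == 0L) {
        nodes[[i]] <- pair_branches(nodes[[i]], sk, config$region_nm)
        nodes[[i]] <- call_crossing_order(nodes[[i]], sk, flat)
      } else {
        paired <- FALSE
      }
    }
    cors <- unlist(lapply(nodes, function(nd)
      if (!is.null(nd$pairs)) nd$cor else NULL))
    out$n_crossings <- sum(vapply(nodes, function(nd)
      if (is.null(nd$pairs)) 0L else length(nd$pairs) %/% 2L, 0L))
    if (length(cors)) {
      out$avg_cor <- mean(cors)
      out$min_cor <- min(cors)
      out$reliable <- min(cors) >= config$cor_threshold
    }
    if (!paired) {
      out$failure <- "unpaired junction node"
      return(list(row = out, nxyz = NULL))
    }
    if (any(vapply(nodes, function(nd) isTRUE(nd$degenerate), TRUE))) {
      out$failure <- "degenerate crossing: no crossing-order signal"
      return(list(row = out, nxyz = NULL))
    }
    traces <- order_trace(sk, nodes)
    nx <- to_nxyz(traces, object_id = gi)
    nxyz <- nx
    closed <- vapply(traces$molecules, function(m) isTRUE(attr(m, "closed")), TRUE)
    lens <- vapply(seq_along(traces$molecules), function(i)
      contour_length(traces$molecules[[i]], ps, closed[i],
                     smooth_px = config$length_smooth_px), 0)
    out$n_molecules <- length(traces$molecules)
    out$has_linear <- any(!closed)
    out$contour_length_nm <- sum(lens)
    out$contour_lengths_nm <- list(lens)
    if (all(closed)) {
      d <- diagram_from_nxyz(nx)
      cor_by_crossing <- crossing_cor_map(d, nodes, ps)
      cls <- classify_diagram(d, cor = cor_by_crossing,
                              max_crossings = config$max_crossings)
      out$rolfsen <- cls$rolfsen
      out$alternate_rolfsen <- cls$alternate_rolfsen
    } else {
      out$failure <- "open molecule in object"
    }
    list(row = out, nxyz = nxyz)
  }, error = function(e) {
    out$failure <- conditionMessage(e)
    list(row = out, nxyz = nxyz)
  })
}

# map diagram crossings to node reliabilities by proximity of the crossing
# point to the node centroids
crossing_cor_map <- function(d, nodes, ps) {
  xy <- attr(d, "crossing_xy")
  if (is.null(xy) || !nrow(xy) || !length(nodes)) return(NULL)
  cents <- t(vapply(nodes, function(nd) nd$centroid, c(0, 0)))  # (row, col)
  cors <- vapply(nodes, function(nd) if (is.na(nd$cor)) 0 else nd$cor, 0)
  out <- stats::setNames(numeric(nrow(xy)), names(d$signs))
  for (k in seq_len(nrow(xy))) {
    dd <- sqrt((cents[, 2] - xy[k, 1])^2 + (cents[, 1] - xy[k, 2])^2)
    out[k] <- cors[which.min(dd)]
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$results), " object(s)\n", sep = "")
  print(x$results[, c("grain", "rolfsen", "n_crossings", "min_cor",
                      "n_molecules", "contour_length_nm", "conformation")])
  invisible(x)
}

#' @rdname tidy.topology_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_objects = nrow(x$results),
    n_classified = sum(x$results$rolfsen != "unclassified", na.rm = TRUE),
    n_reliable = sum(x$results$reliable, na.rm = TRUE),
    mean_contour_nm = mean(x$results$contour_length_nm, na.rm = TRUE)
  )
}
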