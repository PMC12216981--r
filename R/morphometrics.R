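#' Expected contour length of a DNA molecule
#'
#' B-form DNA rises 0.34 nm per base pair, so a plasmid of `bp` base pairs
#' deposits at about `bp * 0.34` nm (e.g. 2260 bp -> 768 nm, 3574 bp ->
#' 1215 nm).
#'
#' @param bp base pairs (>= 0).
#' @param rise_nm_per_bp helical rise per base pair in nm.
#' @param round round to whole nm for reporting (default `TRUE`).
#' @return expected length in nm.
#' @export
expected_length <- function(bp, rise_nm_per_bp = 0.34, round = TRUE) {
  if (any(bp < 0)) stop("base-pair count must be non-negative")
  out <- bp * rise_nm_per_bp
  if (round) round(out) else out
}

#' Percentage error of a length measurement
#'
#' `|predicted - true| / true * 100`.
#'
#' @param predicted measured value.
#' @param true reference value (> 0).
#' @return percentage error.
#' @export
percentage_error <- function(predicted, true) {
  if (any(true <= 0)) stop("true value must be positive")
  abs(predicted - true) / true * 100
}

#' Morphometric statistics of a grain
#'
#' Bounding-box and Feret statistics are computed on the grain mask (not the
#' skeleton): minimum-area rotated bounding box width/length, aspect ratio,
#' and maximum Feret diameter; endpoint and junction counts come from the
#' skeleton degrees.
#'
#' @param mask a `grain_mask`.
#' @param label grain id.
#' @param sk optional `afm_skeleton` of the grain for endpoint/junction
#'   counts.
#' @return a one-row tibble.
#' @export
grain_stats <- function(mask, label = 1L, sk = NULL) {
  px <- which(mask$labels == label, arr.ind = TRUE)
  if (!nrow(px)) stop("grain ", label, " is empty")
  ps <- mask$pixel_size_nm
  pts <- px[, c(2, 1), drop = FALSE] * ps   # (x, y) nm
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  mf <- max_feret(hull)
  bb <- min_bounding_box(hull)
  ep <- jn <- NA_integer_
  if (!is.null(sk)) {
    deg <- skeleton_degree(sk)
    ep <- sum(deg == 1L)
    jn <- length(detect_nodes(sk))
  }
  tibble::tibble(grain = label,
                 area_nm2 = nrow(px) * ps^2,
                 smallest_bounding_width = bb$width,
                 smallest_bounding_length = bb$length,
                 aspect_ratio = bb$length / max(bb$width, 1e-9),
                 max_feret = mf,
                 grain_endpoints = ep,
                 grain_junctions = jn)
}

max_feret <- function(hull) {
  if (nrow(hull) < 2L) return(0)
  d <- as.matrix(stats::dist(hull))
  max(d)
}

# rotating calipers over hull edges
min_bounding_box <- function(hull) {
  n <- nrow(hull)
  if (n < 3L) {
    w <- 0
    l <- max_feret(hull)
    return(list(width = w, length = l))
  }
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    e <- e / sqrt(sum(e^2))
    u <- hull %*% e
    v <- hull %*% c(-e[2], e[1])
    a <- (max(u) - min(u)) * (max(v) - min(v))
    if (is.null(best) || a < best$a) {
      best <- list(a = a, width = min(max(u) - min(u), max(v) - min(v)),
                   length = max(max(u) - min(u), max(v) - min(v)))
    }
  }
  list(width = best$width, length = best$length)
}

#' End-to-end distance of a molecule trace
#'
#' @param trace data frame with `X`, `Y` (pixel coordinates).
#' @param pixel_size_nm nm per pixel.
#' @param closed closed molecules have end-to-end distance 0.
#' @return distance in nm.
#' @export
end_to_end_distance <- function(trace, pixel_size_nm = 1, closed = NULL) {
  if (is.null(closed)) {
    closed <- if ("closed" %in% names(trace)) all(trace$closed)
    else isTRUE(attr(trace, "closed"))
  }
  if (closed) return(0)
  trace <- as.data.frame(trace)
  sqrt((trace$X[1] - trace$X[nrow(trace)])^2 +
       (trace$Y[1] - trace$Y[nrow(trace)])^2) * pixel_size_nm
}

#' Replication-intermediate (theta-structure) analysis
#'
#' Breaks the skeleton at odd-branched junctions (replication forks are
#' 3-way junctions) and measures the resulting segments.  An object with
#' exactly two forks and three segments is a theta structure: a partially
#' replicated circle whose two nascent daughter segments have near-equal
#' length, with the unreplicated parent DNA between the forks.  The
#' unreplicated segment is identified as the one most dissimilar in length
#' from the other two (the segment whose removal leaves the most similar
#' pair); because the two replicated arms replicate in step this is normally
#' also the shortest segment, which is reported alongside.  When the margin
#' between candidate assignments is small the call is flagged low
#' confidence.
#'
#' @param sk an `afm_skeleton` (unpruned or lightly pruned).
#' @param nodes nodes from [detect_nodes()] (not merged across forks).
#' @param margin relative dissimilarity margin below which the call is
#'   flagged low confidence.
#' @return an object of class `theta_analysis`; `is_theta` is `FALSE` when
#'   the object does not have exactly 2 forks and 3 segments.
#' @export
analyze_theta <- function(sk, nodes = detect_nodes(sk), margin = 0.05) {
  g <- sk_graph(sk)
  forks <- Filter(function(nd) nd$n_branches == 3L, nodes)
  in_node <- rep(FALSE, g$n)
  for (nd in nodes) in_node[nd$px] <- TRUE
  segs <- if (any(!in_node)) group_adjacent(g, which(!in_node)) else list()
  seg_lengths <- vapply(segs, function(px) {
    path <- order_segment(g, px)
    path_length_px(g$coords[path, , drop = FALSE]) * g$pixel_size_nm
  }, 0)
  ok <- length(forks) == 2L && length(segs) == 3L
  if (!ok) {
    return(structure(list(is_theta = FALSE, n_forks = length(forks),
                          n_segments = length(segs),
                          segment_lengths_nm = seg_lengths),
                     class = "theta_analysis"))
  }
  l <- seg_lengths
  # candidate i is unreplicated if the other two are the most similar pair
  dis <- vapply(1:3, function(i) abs(diff(l[-i])), 0)
  ord <- order(dis, l)   # ties resolved toward the shortest segment
  unrep <- ord[1]
  low_conf <- (dis[ord[2]] - dis[ord[1]]) < margin * mean(l)
  structure(list(is_theta = TRUE, n_forks = 2L, n_segments = 3L,
                 segment_lengths_nm = l,
                 unreplicated_length_nm = l[unrep],
                 unreplicated_shortest_nm = min(l),
                 replicated_lengths_nm = l[-unrep],
                 low_confidence = low_conf),
            class = "theta_analysis")
}

#' @export
print.theta_analysis <- function(x, ...) {
  if (!x$is_theta) {
    cat("<theta_analysis> not a theta structure (", x$n_forks, " forks, ",
        x$n_segments, " segments)\n", sep = "")
  } else {
    cat("<theta_analysis> theta structure; segments ",
        paste(round(x$segment_lengths_nm, 1), collapse = " / "),
        " nm; unreplicated ", round(x$unreplicated_length_nm, 1), " nm",
        if (isTRUE(x$low_confidence)) " (low confidence)", "\n", sep = "")
  }
  invisible(x)
}

#' Detect reversed replication forks
#'
#' A reversed fork is a 4-way junction with exactly one short (< 50 nm)
#' emanating segment — the extruded regressed arm.  Paired crossings are
#' excluded: all four branches of a crossing continue into the molecule,
#' so none terminates in a short stub.
#'
#' @param sk an `afm_skeleton`.
#' @param nodes nodes from [detect_nodes()].
#' @param max_branch_nm stub length threshold (50 nm).
#' @return a tibble with one row per flagged junction (`node`, `branch_nm`);
#'   zero rows when none found.
#' @export
detect_reversed_fork <- function(sk, nodes = detect_nodes(sk),
                                 max_branch_nm = 50) {
  g <- sk_graph(sk)
  out <- list()
  for (nd in nodes) {
    if (nd$n_branches != 4L) next
    blen <- vapply(nd$branches, function(b) {
      terminating <- g$deg[b[length(b)]] <= 1L
      if (!terminating) return(NA_real_)
      path_length_px(g$coords[b, , drop = FALSE]) * g$pixel_size_nm
    }, 0)
    short <- which(!is.na(blen) & blen < max_branch_nm)
    if (length(short) == 1L) {
      out[[length(out) + 1L]] <- tibble::tibble(node = nd$id,
                                                branch_nm = blen[short])
    }
  }
  if (!length(out)) {
    return(tibble::tibble(node = integer(), branch_nm = numeric()))
  }
  dplyr::bind_rows(out)
}
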