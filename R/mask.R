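#' Grain masking configuration
#'
#' Either an absolute height threshold (nm) or a multiple of the robust
#' background spread can be used; the absolute form takes precedence when
#' both are set.
#'
#' @param threshold_nm absolute height threshold in nm (pixels strictly above
#'   are foreground), or `NULL`.
#' @param threshold_sigma threshold as background median plus this many
#'   robust (MAD) standard deviations.
#' @param min_area_px connected components smaller than this are dropped.
#' @param remove_border drop grains touching the image border.
#' @param connectivity 4 or 8.
#' @return a list of class `mask_config`.
#' @export
mask_config <- function(threshold_nm = NULL, threshold_sigma = 3,
                        min_area_px = 40L, remove_border = FALSE,
                        connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  structure(list(threshold_nm = threshold_nm,
                 threshold_sigma = threshold_sigma,
                 min_area_px = as.integer(min_area_px),
                 remove_border = isTRUE(remove_border),
                 connectivity = as.integer(connectivity)),
            class = "mask_config")
}

#' Label molecules in a flattened height map
#'
#' Thresholds the image and labels connected components (grains) `1..K` in
#' raster order of their first pixel; small components and, optionally,
#' border-touching components are removed.
#'
#' @param hm a flattened `afm_heightmap`.
#' @param cfg a [mask_config()].
#' @return an object of class `grain_mask`: integer label matrix (0 =
#'   background), pixel size and per-label pixel counts.
#' @export
mask_grains <- function(hm, cfg = mask_config()) {
  stopifnot(inherits(hm, "afm_heightmap"))
  h <- hm$heights
  bg_mode <- stats::median(h)
  thr <- if (!is.null(cfg$threshold_nm)) cfg$threshold_nm else {
    s <- stats::mad(h)
    if (s == 0) s <- stats::sd(h)
    bg_mode + cfg$threshold_sigma * s
  }
  if (thr <= bg_mode) {
    warning("threshold ", signif(thr, 3),
            " nm is at or below the background mode; mask is degenerate")
  }
  fg <- h > thr
  labels <- label_components(fg, cfg$connectivity)
  if (max(labels) > 0L &&
      any(tabulate(labels, nbins = max(labels)) > 0.5 * length(h))) {
    warning("a single grain covers most of the image; returning empty mask")
    labels[] <- 0L
  }
  counts <- tabulate(labels, nbins = max(labels))
  drop <- which(counts < cfg$min_area_px)
  if (cfg$remove_border && max(labels) > 0L) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels <- relabel_raster(labels)
  structure(list(labels = labels, pixel_size_nm = hm$pixel_size_nm,
                 counts = tabulate(labels, nbins = max(labels))),
            class = "grain_mask")
}

#' @export
print.grain_mask <- function(x, ...) {
  cat("<grain_mask> ", nrow(x$labels), " x ", ncol(x$labels), " px, ",
      length(x$counts), " grain(s)", sep = "")
  if (length(x$counts)) {
    cat("; areas (px): ", paste(x$counts, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Grains as a tibble
#' @param x a `grain_mask`.
#' @param ... unused.
#' @export
as_tibble.grain_mask <- function(x, ...) {
  k <- length(x$counts)
  tibble::tibble(grain = seq_len(k),
                 area_px = x$counts,
                 area_nm2 = x$counts * x$pixel_size_nm^2)
}

#' @export
as_tibble.afm_heightmap <- function(x, ...) heightmap_df(x)

# connected-component labelling on a logical matrix
label_components <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  if (!any(fg)) return(lab)
  idx <- which(fg)
  node <- match(seq_len(nr * nc), idx)  # pixel linear index -> node id
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- NULL
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (s in shifts) {
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- fg[lin2]
    edges <- rbind(edges, cbind(node[idx[ok][ok2]], node[lin2[ok2]]))
  }
  if (is.null(edges)) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  lab[idx] <- as.integer(mem)
  relabel_raster(lab)
}

# renumber labels 1..K in raster order of first occurrence
relabel_raster <- function(lab) {
  present <- lab[lab > 0L]
  if (!length(present)) return(lab)
  first <- unique(present[order(which(lab > 0L))])
  lab[lab > 0L] <- match(present, first)
  lab
}
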