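#' Order a skeleton into continuous molecule traces
#'
#' Partitions the skeleton into crossing regions (node pixels) and
#' connecting segments, then concatenates segments into per-molecule paths
#' by following the branch pairing through each node: entering a crossing
#' along one branch exits along its paired branch, with the crossing
#' region's pixels assigned the pair's integer pseudo-height.  When a closed
#' tour returns to its starting segment the molecule is complete; leftover
#' segments seed further molecules, which is how entangled molecules
#' (catenanes) are separated.  Segments with a free end yield open (linear)
#' molecules.
#'
#' @param sk a pruned `afm_skeleton`.
#' @param nodes list of `crossing_node`s on `sk`, already paired and with
#'   crossing order called ([pair_branches()], [call_crossing_order()]).
#'   An unpaired node encountered during tracing raises a tracing error.
#' @return an object of class `afm_traces`: a list of per-molecule tibbles
#'   with columns `N`, `X`, `Y`, `Z` (pixel coordinates, `Z` the pseudo
#'   height) and a `closed` attribute each.
#' @export
order_trace <- function(sk, nodes = list()) {
  g <- sk_graph(sk)
  in_node <- rep(FALSE, g$n)
  for (nd in nodes) in_node[nd$px] <- TRUE
  free_idx <- which(!in_node)
  if (!length(free_idx)) stop("skeleton has no connecting segments")
  segs <- lapply(group_adjacent(g, free_idx), function(px) order_segment(g, px))
  # map: for every node branch, which segment end it attaches to
  att_map <- list()   # key "seg:end" -> c(node, branch)
  for (ni in seq_along(nodes)) {
    nd <- nodes[[ni]]
    for (bi in seq_along(nd$branches)) {
      grp <- attachment_group(g, nd, bi)
      for (si in seq_along(segs)) {
        p <- segs[[si]]
        for (e in 1:2) {
          endpx <- if (e == 1L) p[1] else p[length(p)]
          if (endpx %in% grp) att_map[[paste0(si, ":", e)]] <- c(ni, bi)
        }
      }
    }
  }
  node_of_branch <- function(ni, bi) {
    for (si in seq_along(segs)) for (e in 1:2) {
      hit <- att_map[[paste0(si, ":", e)]]
      if (!is.null(hit) && hit[1] == ni && hit[2] == bi) return(c(si, e))
    }
    NULL
  }
  used <- rep(FALSE, length(segs))
  used_node_px <- integer(0)
  molecules <- list()
  repeat {
    remaining <- which(!used)
    if (!length(remaining)) break
    # prefer open starts (a segment end not attached to any node)
    start <- NULL
    for (si in remaining) {
      for (e in 1:2) {
        if (is.null(att_map[[paste0(si, ":", e)]])) {
          start <- c(si, e); break
        }
      }
      if (!is.null(start)) break
    }
    open_start <- !is.null(start)
    if (is.null(start)) {
      lows <- vapply(remaining, function(si) min(segs[[si]]), 0L)
      si <- remaining[which.min(lows)]
      p <- segs[[si]]
      ends <- g$coords[c(p[1], p[length(p)]), , drop = FALSE]
      e <- if (ends[1, 1] < ends[2, 1] ||
               (ends[1, 1] == ends[2, 1] && ends[1, 2] <= ends[2, 2])) 1L else 2L
      start <- c(si, e)
    }
    rec <- trace_one(g, segs, att_map, nodes, start, used, used_node_px,
                     open_start)
    used <- rec$used
    used_node_px <- rec$used_node_px
    molecules[[length(molecules) + 1L]] <- rec$molecule
  }
  structure(list(molecules = molecules,
                 pixel_size_nm = g$pixel_size_nm,
                 grain = attr(sk, "grain")),
            class = "afm_traces")
}

attachment_group <- function(g, nd, bi) {
  in_node <- rep(FALSE, g$n); in_node[nd$px] <- TRUE
  first <- nd$branches[[bi]][1]
  att <- unique(unlist(lapply(nd$px, function(p) {
    nb <- sk_neighbors(g, p)
    nb[!in_node[nb]]
  })))
  for (grp in group_adjacent(g, sort(att))) {
    if (first %in% grp) return(grp)
  }
  first
}

order_segment <- function(g, px) {
  if (length(px) == 1L) return(px)
  in_seg <- rep(FALSE, g$n); in_seg[px] <- TRUE
  deg_in <- vapply(px, function(p) sum(in_seg[sk_neighbors(g, p)]), 0L)
  ends <- px[deg_in <= 1L]
  start <- if (length(ends)) min(ends) else min(px)   # cycle: raster start
  path <- integer(0)
  cur <- start; prev <- 0L
  repeat {
    path <- c(path, cur)
    nb <- sk_neighbors(g, cur)
    nb <- nb[in_seg[nb] & nb != prev & !(nb %in% path)]
    if (!length(nb)) break
    prev <- cur
    cur <- nb[1]
  }
  path
}

trace_one <- function(g, segs, att_map, nodes, start, used, used_node_px,
                      open_start) {
  px_size <- g$pixel_size_nm
  rows <- list()
  si <- start[1]; e <- start[2]
  start_key <- paste0(si, ":", e)
  closed <- FALSE
  hit_node <- FALSE
  repeat {
    p <- segs[[si]]
    if (e == 2L) p <- rev(p)
    used[si] <- TRUE
    co <- g$coords[p, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(X = co[, 2], Y = co[, 1], Z = 0)
    exit_end <- if (e == 1L) 2L else 1L
    hit <- att_map[[paste0(si, ":", exit_end)]]
    if (is.null(hit)) break   # open molecule
    hit_node <- TRUE
    nd <- nodes[[hit[1]]]
    if (is.null(nd$pairs)) {
      stop(structure(class = c("topotrace_tracing_error", "error", "condition"),
                     list(message = paste0("trace reached unpaired node ",
                                           nd$id, " (junction)"),
                          call = sys.call())))
    }
    bi <- hit[2]
    k <- which(vapply(nd$pairs, function(pr) bi %in% pr, TRUE))[1]
    if (is.na(k)) {
      stop(structure(class = c("topotrace_tracing_error", "error", "condition"),
                     list(message = paste0("branch ", bi, " of node ", nd$id,
                                           " is unpaired"),
                        call = sys.call())))
    }
    pr <- nd$pairs[[k]]
    b2 <- if (pr[1] == bi) pr[2] else pr[1]
    interior <- nd$through[[k]]
    in_node_px <- interior[interior %in% nd$px]
    if (pr[2] == bi) in_node_px <- rev(in_node_px)
    if (length(in_node_px)) {
      co_n <- g$coords[in_node_px, , drop = FALSE]
      xy <- data.frame(X = co_n[, 2], Y = co_n[, 1],
                       Z = nd$pseudo_z[k])
      dup <- in_node_px %in% used_node_px
      if (any(dup)) {
        # nudge re-used crossing pixels off the lattice so the projected
        # polylines cross transversally rather than touching
        dirv <- co_n[nrow(co_n), ] - co_n[1, ]
        nv <- sqrt(sum(dirv^2))
        if (nv < 1e-9) dirv <- c(1, 0) else dirv <- dirv / nv
        xy$X[dup] <- xy$X[dup] - 0.35 * dirv[1]
        xy$Y[dup] <- xy$Y[dup] + 0.35 * dirv[2]
      }
      used_node_px <- union(used_node_px, in_node_px)
      rows[[length(rows) + 1L]] <- xy
    }
    # continue along the partner branch's segment
    nxt <- NULL
    for (si2 in seq_along(segs)) for (e2 in 1:2) {
      hit2 <- att_map[[paste0(si2, ":", e2)]]
      if (!is.null(hit2) && hit2[1] == hit[1] && hit2[2] == b2) {
        nxt <- c(si2, e2)
      }
    }
    if (is.null(nxt)) {
      stop(structure(class = c("topotrace_tracing_error", "error", "condition"),
                     list(message = paste0("no segment attached to branch ",
                                           b2, " of node ", nd$id),
                          call = sys.call())))
    }
    if (paste0(nxt[1], ":", nxt[2]) == start_key) {
      closed <- TRUE
      break
    }
    if (used[nxt[1]]) {
      stop(structure(class = c("topotrace_tracing_error", "error", "condition"),
                     list(message = paste0("trace revisits segment ", nxt[1],
                                           "; branch pairing is inconsistent"),
                          call = sys.call())))
    }
    si <- nxt[1]; e <- nxt[2]
  }
  mol <- do.call(rbind, rows)
  mol <- tibble::as_tibble(mol)
  mol$N <- seq_len(nrow(mol)) - 1L
  mol <- mol[, c("N", "X", "Y", "Z")]
  if (!closed && !hit_node && nrow(mol) > 2L) {
    # a node-free cycle: the ordered segment ends next to its start
    closed <- max(abs(c(mol$X[1] - mol$X[nrow(mol)],
                        mol$Y[1] - mol$Y[nrow(mol)]))) <= 1.5
  }
  attr(mol, "closed") <- closed
  list(molecule = mol, used = used, used_node_px = used_node_px)
}

#' @export
print.afm_traces <- function(x, ...) {
  cat("<afm_traces> ", length(x$molecules), " molecule(s)",
      if (!is.na(x$grain)) paste0(" in grain ", x$grain), ":\n", sep = "")
  for (i in seq_along(x$molecules)) {
    m <- x$molecules[[i]]
    cat("  molecule ", i, ": ", nrow(m), " px, ",
        if (isTRUE(attr(m, "closed"))) "closed" else "open", "\n", sep = "")
  }
  invisible(x)
}

#' NXYZ table of ordered traces
#'
#' Flattens traces to the NXYZ interchange format: per molecule the ordered
#' index `N` (re-indexed from 0 for every molecule), pixel coordinates `X`,
#' `Y` and pseudo-height `Z` (nonzero only inside crossing regions, encoding
#' the crossing order as ascending integers).
#'
#' @param traces an `afm_traces` object.
#' @param object_id identifier column value (defaults to the grain id).
#' @return a tibble with columns `object_id`, `molecule_id`, `N`, `X`, `Y`,
#'   `Z`, `closed`.
#' @export
to_nxyz <- function(traces, object_id = NULL) {
  stopifnot(inherits(traces, "afm_traces"))
  if (is.null(object_id)) object_id <- attr(traces, "grain") %||% traces$grain
  if (is.null(object_id) || is.na(object_id)) object_id <- 1L
  out <- lapply(seq_along(traces$molecules), function(i) {
    m <- traces$molecules[[i]]
    tibble::tibble(object_id = object_id, molecule_id = i,
                   N = m$N, X = m$X, Y = m$Y, Z = m$Z,
                   closed = isTRUE(attr(m, "closed")))
  })
  dplyr::bind_rows(out)
}

#' Contour length of a molecule trace
#'
#' Sum of the step lengths between consecutive trace points (1 px for axial
#' steps, sqrt(2) px for diagonal), scaled by the pixel size; the closing
#' step back to the start is included for closed molecules.
#'
#' An 8-connected pixel chain systematically overestimates the length of a
#' smooth curve by a few percent (staircase inflation); `smooth_px > 1`
#' applies a circular moving average of that window to the coordinates
#' before summing steps, which removes most of the bias.  The default 1
#' reproduces the raw step sum.
#'
#' @param trace one molecule: a data frame with `X`, `Y` columns (pixel
#'   coordinates), or rows of an NXYZ table for one molecule.
#' @param pixel_size_nm nm per pixel.
#' @param closed is the molecule a closed loop?  Defaults to the trace's
#'   `closed` attribute/column, else `TRUE`.
#' @param smooth_px moving-average window (px) applied to the path before
#'   measuring; 1 = none.
#' @return contour length in nm.
#' @export
contour_length <- function(trace, pixel_size_nm = 1, closed = NULL,
                           smooth_px = 1L) {
  if (is.null(closed)) {
    closed <- if ("closed" %in% names(trace)) all(trace$closed)
    else if (!is.null(attr(trace, "closed"))) isTRUE(attr(trace, "closed"))
    else TRUE
  }
  trace <- as.data.frame(trace)
  if (nrow(trace) < 3L) stop("trace too short for a contour length")
  xy <- cbind(trace$X, trace$Y)
  if (smooth_px > 1L) xy <- smooth_path(xy, smooth_px, closed)
  d <- sqrt(rowSums(diff(xy)^2))
  if (closed) d <- c(d, sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)))
  sum(d) * pixel_size_nm
}

smooth_path <- function(xy, w, closed) {
  n <- nrow(xy)
  if (n < w + 2L) return(xy)
  half <- (w - 1L) %/% 2L
  if (closed) {
    ext <- rbind(xy[(n - half + 1L):n, , drop = FALSE], xy,
                 xy[1:half, , drop = FALSE])
    out <- matrix(0, n, 2)
    for (j in 1:2) {
      cs <- cumsum(c(0, ext[, j]))
      out[, j] <- (cs[(w + 1L):(w + n)] - cs[1:n]) / w
    }
    out
  } else {
    out <- xy
    for (j in 1:2) {
      sm <- stats::filter(xy[, j], rep(1 / w, w), sides = 2)
      out[, j] <- ifelse(is.na(sm), xy[, j], sm)
    }
    out
  }
}
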