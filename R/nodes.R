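#' Detect crossing nodes and junctions in a skeleton
#'
#' Pixels with three or more skeleton neighbours (backbone pixels have
#' exactly two) are grouped by 8-adjacency into nodes.  A node with four
#' emanating branches is a candidate crossing; a node with three branches is
#' a junction (e.g. a replication fork) and is never paired.
#'
#' @param sk a pruned `afm_skeleton`.
#' @return a list of `crossing_node` objects (possibly empty): each carries
#'   its pixel set, centroid, and the emanating branch paths (ordered
#'   outward from the node).
#' @export
detect_nodes <- function(sk) {
  g <- sk_graph(sk)
  cand <- which(g$deg >= 3L)
  if (!length(cand)) return(list())
  groups <- group_adjacent(g, cand)
  nodes <- lapply(seq_along(groups), function(i) {
    node_from_pixels(g, groups[[i]], id = i)
  })
  order_nodes(nodes)
}

group_adjacent <- function(g, idx) {
  in_set <- rep(FALSE, g$n); in_set[idx] <- TRUE
  seen <- rep(FALSE, g$n)
  groups <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- s; seen[s] <- TRUE; queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in sk_neighbors(g, cur)) {
        if (in_set[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          comp <- c(comp, nb)
          queue <- c(queue, nb)
        }
      }
    }
    groups[[length(groups) + 1L]] <- sort(comp)
  }
  groups
}

node_from_pixels <- function(g, px, id = NA_integer_) {
  in_node <- rep(FALSE, g$n); in_node[px] <- TRUE
  # attachment pixels: skeleton neighbours of the node that are not node
  # pixels; mutually adjacent attachments belong to one emanating branch
  att <- unique(unlist(lapply(px, function(p) {
    nb <- sk_neighbors(g, p)
    nb[!in_node[nb]]
  })))
  att <- sort(att)
  branches <- list()
  if (length(att)) {
    agrp <- group_adjacent(g, att)
    for (a in agrp) {
      rep_px <- a[1]
      prev <- px[which(vapply(px, function(p) rep_px %in% sk_neighbors(g, p), TRUE))][1]
      w <- walk_branch_avoiding(g, rep_px, avoid = in_node, prev = prev)
      branches[[length(branches) + 1L]] <- w
    }
  }
  structure(list(id = id, px = sort(px),
                 coords = g$coords[sort(px), , drop = FALSE],
                 centroid = colMeans(g$coords[px, , drop = FALSE]),
                 branches = branches,
                 n_branches = length(branches),
                 parity = if (length(branches) %% 2L == 0L) "even" else "odd",
                 pairs = NULL, cor = NA_real_, degenerate = FALSE),
            class = "crossing_node")
}

# walk outward from an attachment pixel, never stepping back into the node,
# stopping before any pixel of degree >= 3 (another node or this one again)
walk_branch_avoiding <- function(g, start, avoid, prev = 0L) {
  path <- integer(0)
  cur <- start
  repeat {
    path <- c(path, cur)
    if (length(path) > g$n) stop("branch walk failed to terminate")
    nb <- sk_neighbors(g, cur)
    nb <- nb[nb != prev & !avoid[nb]]
    if (length(path) > 1L) nb <- nb[nb != path[length(path) - 1L]]
    if (!length(nb)) return(path)
    nxt <- nb[1]
    if (g$deg[nxt] >= 3L) return(path)
    prev <- cur
    cur <- nxt
  }
}

#' @export
print.crossing_node <- function(x, ...) {
  cat("<crossing_node> id ", x$id, ": ", length(x$px), " px, ",
      x$n_branches, " branches (", x$parity, ")", sep = "")
  if (!is.null(x$pairs)) {
    cat("; FWHM [", paste(round(x$fwhm_nm, 2), collapse = ", "), "] nm, COR ",
        round(x$cor, 3), if (x$degenerate) " (degenerate)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Merge nearby crossing nodes and connect odd-branched nodes
#'
#' Crossing points separated by up to `merge_dist_nm` (about twice the
#' tip-convolved DNA width) likely belong to one physical crossing: their
#' pixel sets, together with the skeleton path joining them, are unioned.
#' Additionally, the shortest skeleton path between two nodes with an odd
#' number of emanating branches (a signature of insensitive segmentation
#' splitting one crossing into two 3-branch nodes) is absorbed so that
#' merged nodes have even branch parity where possible.
#'
#' @param nodes list of `crossing_node` from [detect_nodes()].
#' @param sk the skeleton the nodes came from.
#' @param merge_dist_nm merge distance in nm (default 7).
#' @param connect_odd also connect odd-parity node pairs along the skeleton.
#' @return a list of merged `crossing_node` objects.
#' @export
merge_close_nodes <- function(nodes, sk, merge_dist_nm = 7,
                              connect_odd = TRUE) {
  if (length(nodes) <= 1L && !connect_odd) return(order_nodes(nodes))
  g <- sk_graph(sk)
  px_sets <- lapply(nodes, function(nd) nd$px)
  repeat {
    k <- length(px_sets)
    merged <- FALSE
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          if (min_set_dist(g, px_sets[[i]], px_sets[[j]]) * g$pixel_size_nm <=
              merge_dist_nm) {
            px_sets[[i]] <- union_with_path(g, px_sets[[i]], px_sets[[j]])
            px_sets[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  if (connect_odd) {
    repeat {
      cur <- lapply(seq_along(px_sets), function(i)
        node_from_pixels(g, px_sets[[i]], i))
      odd <- which(vapply(cur, function(nd) nd$parity == "odd", TRUE))
      if (length(odd) < 2L) break
      # closest odd pair along the skeleton
      best <- NULL; best_len <- Inf
      for (a in seq_along(odd)) for (b in seq_along(odd)) {
        if (a >= b) next
        p <- sk_shortest_path(g, px_sets[[odd[a]]], px_sets[[odd[b]]])
        if (!is.null(p) && length(p) < best_len) {
          best <- c(odd[a], odd[b]); best_len <- length(p)
        }
      }
      if (is.null(best)) break
      px_sets[[best[1]]] <- union_with_path(g, px_sets[[best[1]]],
                                            px_sets[[best[2]]])
      px_sets[[best[2]]] <- NULL
    }
  }
  out <- lapply(seq_along(px_sets), function(i)
    node_from_pixels(g, px_sets[[i]], i))
  order_nodes(out)
}

min_set_dist <- function(g, a, b) {
  ca <- g$coords[a, , drop = FALSE]
  cb <- g$coords[b, , drop = FALSE]
  min(sqrt(outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2))
}

union_with_path <- function(g, a, b) {
  p <- sk_shortest_path(g, a, b)
  sort(unique(c(a, b, p)))
}

# deterministic node ids by centroid raster order
order_nodes <- function(nodes) {
  if (!length(nodes)) return(nodes)
  cent <- t(vapply(nodes, function(nd) nd$centroid, c(0, 0)))
  ord <- order(cent[, 1], cent[, 2])
  nodes <- nodes[ord]
  for (i in seq_along(nodes)) nodes[[i]]$id <- i
  nodes
}
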