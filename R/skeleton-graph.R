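# Internal pixel-graph utilities shared by pruning, node detection and
# tracing.  A skeleton is viewed as a graph over its pixels with
# 8-neighbourhood adjacency.

sk_graph <- function(sk) {
  d <- attr(sk, "dim_px")
  n <- nrow(sk)
  im <- matrix(0L, d[1] + 2L, d[2] + 2L)   # padded index matrix
  im[cbind(sk$row + 2L, sk$col + 2L)] <- seq_len(n)
  npr <- nrow(im)
  off <- c(-1L, npr - 1L, npr, npr + 1L, 1L, -npr + 1L, -npr, -npr - 1L)
  lin <- (sk$col + 1L) * npr + sk$row + 2L
  nbr <- matrix(0L, n, 8L)
  for (k in 1:8) nbr[, k] <- im[lin + off[k]]
  deg <- rowSums(nbr > 0L)
  list(n = n, nbr = nbr, deg = deg, im = im, lin = lin,
       coords = cbind(row = sk$row, col = sk$col),
       height = sk$height_nm,
       pixel_size_nm = attr(sk, "pixel_size_nm"))
}

sk_neighbors <- function(g, i) {
  v <- g$nbr[i, ]
  v[v > 0L]
}

# walk from an endpoint (or from `start` away from `prev`) along degree-<=2
# pixels; stops before the first pixel with degree >= 3 (returned separately)
walk_branch <- function(g, start, prev = 0L) {
  path <- integer(0)
  cur <- start
  repeat {
    path <- c(path, cur)
    nb <- sk_neighbors(g, cur)
    nb <- nb[nb != prev]
    if (length(path) > 1L) nb <- nb[nb != path[length(path) - 1L]]
    if (length(nb) == 0L) return(list(path = path, junction = 0L))
    if (g$deg[cur] >= 3L && length(path) > 1L) {
      # stepped onto a junction pixel: stop with it excluded
      return(list(path = path[-length(path)], junction = cur))
    }
    nxt <- nb[1]
    if (g$deg[nxt] >= 3L) return(list(path = path, junction = nxt))
    prev <- cur
    cur <- nxt
    if (length(path) > g$n) stop("branch walk failed to terminate")
  }
}

# arc length (in px units) along an ordered pixel path
path_length_px <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums((coords[-1, , drop = FALSE] -
                    coords[-nrow(coords), , drop = FALSE])^2)))
}

# BFS shortest path between two pixel sets restricted to `allowed` indices;
# returns the path (including both ends) or NULL
sk_shortest_path <- function(g, from, to, allowed = NULL) {
  if (is.null(allowed)) allowed <- rep(TRUE, g$n)
  ok <- allowed
  dist <- rep(NA_integer_, g$n)
  par <- integer(g$n)
  queue <- from[ok[from]]
  dist[queue] <- 0L
  head <- 1L
  to_set <- rep(FALSE, g$n); to_set[to] <- TRUE
  while (head <= length(queue)) {
    cur <- queue[head]; head <- head + 1L
    if (to_set[cur]) {
      path <- cur
      while (par[cur] != 0L) {
        cur <- par[cur]
        path <- c(cur, path)
      }
      return(path)
    }
    for (nb in sk_neighbors(g, cur)) {
      if (ok[nb] && is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        par[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  NULL
}
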