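#' Pair emanating branches of a crossing node
#'
#' Within the crossing region (20 nm by default, below the DNA persistence
#' length), each emanating branch is given a unit propagation vector fitted
#' to its clipped pixel path and oriented away from the node.  Branches are
#' then paired by exact maximum-weight perfect matching with weight
#' `-cos(angle)` between the two vectors, so the most anti-parallel branches
#' — the ones that continue through each other — are paired.
#'
#' @param node a `crossing_node`.
#' @param sk the skeleton the node was detected on.
#' @param region_nm diameter of the crossing region used for the vector fit.
#' @return the node with a `pairs` element (list of index pairs into
#'   `node$branches`) and per-branch clipped paths and vectors.
#' @export
pair_branches <- function(node, sk, region_nm = 20) {
  stopifnot(inherits(node, "crossing_node"))
  nb <- node$n_branches
  if (nb < 4L || nb %% 2L != 0L) {
    stop(structure(class = c("topotrace_parity_error", "error", "condition"),
                   list(message = paste0("node ", node$id, " has ", nb,
                                         " branches; only even counts of at least 4 can be paired"),
                        call = sys.call())))
  }
  g <- sk_graph(sk)
  clip_px <- (region_nm / 2) / g$pixel_size_nm
  clips <- lapply(node$branches, function(b) clip_path(g, b, clip_px))
  vecs <- t(vapply(seq_along(clips), function(i) {
    branch_vector(g, clips[[i]], node$centroid)
  }, c(0, 0)))
  w <- -(vecs %*% t(vecs))
  diag(w) <- -Inf
  pairs <- max_weight_perfect_matching(w)
  node$pairs <- pairs
  node$clips <- clips
  node$vectors <- vecs
  node
}

clip_path <- function(g, path, max_px) {
  co <- g$coords[path, , drop = FALSE]
  if (nrow(co) < 2L) return(path)
  d <- cumsum(c(0, sqrt(rowSums(diff(co)^2))))
  path[d <= max_px]
}

branch_vector <- function(g, path, centroid) {
  co <- g$coords[path, , drop = FALSE]
  if (nrow(co) == 1L) {
    v <- co[1, ] - centroid
  } else {
    cc <- sweep(co, 2, colMeans(co))
    v <- svd(cc, nu = 0, nv = 1)$v[, 1]
    # orient away from the node
    if (sum(v * (co[nrow(co), ] - co[1, ])) < 0) v <- -v
  }
  v / sqrt(sum(v^2))
}

#' Exact maximum-weight perfect matching by enumeration
#'
#' @param w symmetric weight matrix (even dimension).
#' @return list of index pairs; the first strictly-better matching found is
#'   kept, with candidates enumerated in lexicographic branch order so ties
#'   resolve deterministically.
#' @keywords internal
max_weight_perfect_matching <- function(w) {
  n <- nrow(w)
  stopifnot(n %% 2L == 0L)
  if (n > 12L) stop("matching enumeration limited to 12 branches")
  best <- list(score = -Inf, pairs = NULL)
  recurse <- function(free, pairs, score) {
    if (!length(free)) {
      if (score > best$score + 1e-12) best <<- list(score = score, pairs = pairs)
      return()
    }
    a <- free[1]
    for (b in free[-1]) {
      recurse(setdiff(free, c(a, b)), c(pairs, list(c(a, b))),
              score + w[a, b])
    }
  }
  recurse(seq_len(n), list(), 0)
  best$pairs
}

#' Call the crossing order of a paired node from FWHM
#'
#' For every branch pair, the height profile is sampled along the skeleton
#' path branch-a -> node -> branch-b and its full width at half maximum
#' computed (arc length where the height exceeds the profile baseline plus
#' half the peak prominence, with linear interpolation at the half-maximum
#' crossings).  The pair with the maximal FWHM is the over-passing duplex —
#' an over strand bridges the crossing in a wide "humpback" profile while an
#' under strand shows only a narrow spike where the other duplex covers it.
#' Pseudo-heights are assigned as ascending integer ranks (1 = deepest
#' under).  Equal FWHMs, or a profile with no peak above the background,
#' flag the node as degenerate with reliability 0.
#'
#' @param node a paired `crossing_node` (see [pair_branches()]).
#' @param sk the skeleton.
#' @param hm the flattened height map.
#' @return the node with `fwhm_nm`, `pseudo_z`, `over_pair`, `cor`,
#'   `degenerate` and per-pair through-paths filled in.
#' @export
call_crossing_order <- function(node, sk, hm) {
  stopifnot(inherits(node, "crossing_node"), !is.null(node$pairs))
  g <- sk_graph(sk)
  in_node <- rep(FALSE, g$n); in_node[node$px] <- TRUE
  fwhm <- numeric(length(node$pairs))
  through <- vector("list", length(node$pairs))
  for (k in seq_along(node$pairs)) {
    pr <- node$pairs[[k]]
    a <- node$clips[[pr[1]]]
    b <- node$clips[[pr[2]]]
    allowed <- in_node
    allowed[c(a[1], b[1])] <- TRUE
    np <- sk_shortest_path(g, a[1], b[1], allowed = allowed)
    if (is.null(np)) np <- c(a[1], b[1])
    mid <- np[!(np %in% c(a[1], b[1]))]
    path <- c(rev(a), a[1], mid, b[1], b)
    path <- path[!duplicated(path)]
    through[[k]] <- path
    co <- g$coords[path, , drop = FALSE]
    s <- cumsum(c(0, sqrt(rowSums(diff(co)^2)))) * g$pixel_size_nm
    h <- hm$heights[co + 1L]
    fwhm[k] <- profile_fwhm(s, h)
  }
  node$through <- through
  node$fwhm_nm <- fwhm
  if (anyNA(fwhm)) {
    node$degenerate <- TRUE
    node$cor <- 0
    fwhm[is.na(fwhm)] <- 0
  } else {
    node$degenerate <- length(fwhm) > 1L &&
      diff(sort(fwhm, decreasing = TRUE)[2:1]) < 1e-9
    node$cor <- if (node$degenerate && all(abs(diff(fwhm)) < 1e-9)) 0 else
      crossing_order_reliability(pmax(fwhm, 1e-12))
  }
  node$pseudo_z <- rank(fwhm, ties.method = "first")
  node$over_pair <- which.max(node$pseudo_z)
  node
}

#' Full width at half maximum of a height profile
#'
#' The baseline is the minimum of the profile (the duplex shoulder when the
#' trace is clipped to the crossing region, the substrate for an isolated
#' peak); the peak must rise above the flattened-image background (0 nm) to
#' be valid.  Half-maximum positions are linearly interpolated.
#'
#' @param s arc length (nm), increasing.
#' @param h heights (nm) at `s`.
#' @param min_prominence_nm minimum peak prominence above the baseline for a
#'   valid crossing peak; below this the crossing carries no usable
#'   crossing-order signal (e.g. a crossing compressed to single-duplex
#'   height) and `NA` is returned.
#' @return FWHM in nm, or `NA` for a flat profile or one with no peak above
#'   the background.
#' @export
profile_fwhm <- function(s, h, min_prominence_nm = 0.1) {
  stopifnot(length(s) == length(h), length(s) >= 3L)
  base <- min(h)
  peak <- max(h)
  if (peak <= 0 || peak - base < min_prominence_nm) return(NA_real_)
  half <- base + (peak - base) / 2
  ip <- which.max(h)
  left <- s[1]
  if (ip > 1L) {
    for (i in ip:2L) {
      if (h[i - 1L] < half) {
        left <- s[i - 1L] + (s[i] - s[i - 1L]) * (half - h[i - 1L]) / (h[i] - h[i - 1L])
        break
      }
    }
  }
  right <- s[length(s)]
  if (ip < length(h)) {
    for (i in ip:(length(h) - 1L)) {
      if (h[i + 1L] < half) {
        right <- s[i] + (s[i + 1L] - s[i]) * (h[i] - half) / (h[i] - h[i + 1L])
        break
      }
    }
  }
  right - left
}

#' Average crossing order reliability
#'
#' For a crossing with duplex FWHM values `f`, every unordered pair
#' contributes `1 - min/max`; the reliability is the mean over all `C(k, 2)`
#' pairings, in `[0, 1]`.  Equal widths give 0 (an uninformative crossing);
#' a large width ratio approaches 1.  The value is invariant to rescaling
#' all FWHMs.
#'
#' @param fwhms numeric vector (length >= 2) of positive FWHM values, one
#'   per duplex passing through the crossing.
#' @return the average crossing order reliability.
#' @examples
#' crossing_order_reliability(c(0.2, 0.5))       # 0.6
#' crossing_order_reliability(c(0.2, 0.5, 0.7))  # 0.53
#' @export
crossing_order_reliability <- function(fwhms) {
  if (length(fwhms) < 2L) stop("need at least two FWHM values")
  if (any(!is.finite(fwhms)) || any(fwhms <= 0)) {
    stop("FWHM values must be positive and finite")
  }
  prs <- utils::combn(fwhms, 2L)
  mean(1 - apply(prs, 2L, min) / apply(prs, 2L, max))
}
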