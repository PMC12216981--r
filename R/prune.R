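#' Prune spurious skeleton branches
#'
#' Removes terminating branches (paths from a degree-1 endpoint to the first
#' junction pixel) that are artefacts of thinning rather than molecule arms:
#' branches shorter than `length_frac` of the total skeleton pixel count, and
#' branches whose centre-pixel height falls more than `height_drop_nm` below
#' the mean height of the skeleton backbone (0.85 nm, the depth of the DNA
#' major groove, by default — a branch that much lower than the duplex ridge
#' is mask overspill, not DNA).  The two rules are applied in that order and
#' repeated until the skeleton is stable.  A skeleton that is a pure cycle or
#' a single open path is returned unchanged.
#'
#' @param sk an `afm_skeleton`.
#' @param length_frac branch-length threshold as a fraction of skeleton size.
#' @param height_drop_nm height threshold below the backbone mean.
#' @return the pruned `afm_skeleton`.
#' @export
prune_skeleton <- function(sk, length_frac = 0.15, height_drop_nm = 0.85) {
  keep <- rep(TRUE, nrow(sk))
  repeat {
    cur <- sk[keep, , drop = FALSE]
    cur <- new_skeleton(cur, attr(sk, "dim_px"), attr(sk, "pixel_size_nm"),
                        attr(sk, "grain"))
    g <- sk_graph(cur)
    eps <- which(g$deg == 1L)
    if (!length(eps)) break
    branches <- list()
    for (e in eps) {
      w <- walk_branch(g, e)
      if (w$junction == 0L) next          # open path, not a terminating branch
      branches[[length(branches) + 1L]] <- w$path
    }
    if (!length(branches)) break
    lens <- vapply(branches, length, 0L)
    short <- lens < length_frac * g$n
    drop_idx <- NULL
    if (any(short)) {
      drop_idx <- unlist(branches[short])
    } else {
      in_branch <- rep(FALSE, g$n)
      in_branch[unlist(branches)] <- TRUE
      backbone_mean <- mean(g$height[!in_branch])
      for (b in branches) {
        mid <- b[ceiling(length(b) / 2)]
        if (g$height[mid] < backbone_mean - height_drop_nm) {
          drop_idx <- c(drop_idx, b)
        }
      }
    }
    if (is.null(drop_idx)) break
    # map back to positions in the original tibble
    keep_pos <- which(keep)
    keep[keep_pos[unique(drop_idx)]] <- FALSE
  }
  out <- sk[keep, , drop = FALSE]
  new_skeleton(out, attr(sk, "dim_px"), attr(sk, "pixel_size_nm"),
               attr(sk, "grain"))
}
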