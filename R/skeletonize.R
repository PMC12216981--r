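#' Height-biased skeletonisation of a grain
#'
#' Reduces a labelled grain to a single-pixel-wide 8-connected skeleton by
#' iterative boundary thinning (Zhang–Suen).  The variation here exploits the
#' height data of the AFM image: among the simultaneously deletable boundary
#' pixels of each sub-iteration, lower pixels are deleted first (sequentially,
#' re-checking deletability against the current image), so the surviving
#' ridge follows the height maximum of the molecule rather than its
#' geometric centre — important where the mask bulges at crossings.
#' With `height_bias = FALSE` the classic simultaneous-deletion algorithm is
#' used instead (the comparison baseline).
#'
#' A final cleanup removes redundant staircase pixels so that pixel degree on
#' the 8-neighbourhood is meaningful (backbone pixels have exactly two
#' neighbours).
#'
#' @param mask a `grain_mask`.
#' @param hm the flattened `afm_heightmap` the mask was derived from.
#' @param label grain id to skeletonise.
#' @param height_bias delete lower pixels first (default `TRUE`).
#' @return an `afm_skeleton`: a tibble with columns `row`, `col` (0-based)
#'   and `height_nm`, carrying the image dimensions, pixel size and grain id
#'   as attributes.
#' @export
skeletonize_height_biased <- function(mask, hm, label = 1L,
                                      height_bias = TRUE) {
  stopifnot(inherits(mask, "grain_mask"), inherits(hm, "afm_heightmap"))
  B <- mask$labels == label
  if (!any(B)) stop("grain ", label, " is empty")
  H <- hm$heights
  nr <- nrow(B); nc <- ncol(B)
  # pad to avoid bounds checks
  Bp <- matrix(FALSE, nr + 2L, nc + 2L)
  Bp[2:(nr + 1L), 2:(nc + 1L)] <- B
  Hp <- matrix(-Inf, nr + 2L, nc + 2L)
  Hp[2:(nr + 1L), 2:(nc + 1L)] <- H
  Bp <- zhang_suen(Bp, Hp, height_bias)
  Bp <- remove_staircase(Bp)
  idx <- which(Bp)
  npr <- nrow(Bp)
  rows <- ((idx - 1L) %% npr) + 1L - 1L   # back to unpadded, 0-based
  cols <- ((idx - 1L) %/% npr) + 1L - 1L
  ord <- order(rows, cols)
  new_skeleton(
    tibble::tibble(row = rows[ord] - 1L, col = cols[ord] - 1L,
                   height_nm = Hp[idx][ord]),
    dim = c(nr, nc), pixel_size_nm = hm$pixel_size_nm, grain = label
  )
}

new_skeleton <- function(px, dim, pixel_size_nm, grain = NA_integer_) {
  structure(px, class = c("afm_skeleton", class(px)),
            dim_px = dim, pixel_size_nm = pixel_size_nm, grain = grain)
}

#' @export
print.afm_skeleton <- function(x, ...) {
  cat("<afm_skeleton> ", nrow(x), " px, grain ", attr(x, "grain"),
      ", ", attr(x, "pixel_size_nm"), " nm/px\n", sep = "")
  NextMethod()
}

# logical matrix (padded coordinates) from a skeleton tibble
skeleton_matrix <- function(sk) {
  d <- attr(sk, "dim_px")
  m <- matrix(FALSE, d[1], d[2])
  m[cbind(sk$row + 1L, sk$col + 1L)] <- TRUE
  m
}

skeleton_from_matrix <- function(m, sk_template, H = NULL) {
  idx <- which(m)
  nr <- nrow(m)
  rows <- ((idx - 1L) %% nr)
  cols <- ((idx - 1L) %/% nr)
  ord <- order(rows, cols)
  hts <- if (is.null(H)) {
    key <- paste(rows, cols)
    old <- stats::setNames(sk_template$height_nm,
                           paste(sk_template$row, sk_template$col))
    unname(old[key])
  } else H[idx]
  new_skeleton(
    tibble::tibble(row = rows[ord], col = cols[ord], height_nm = hts[ord]),
    dim = attr(sk_template, "dim_px"),
    pixel_size_nm = attr(sk_template, "pixel_size_nm"),
    grain = attr(sk_template, "grain")
  )
}

# Zhang-Suen thinning on a padded logical matrix.
#
# Unbiased: the classic two sub-iteration simultaneous-deletion algorithm.
# Height-biased: per iteration the deletable boundary pixels of both
# sub-iterations are pooled and deleted sequentially in ascending height
# order, re-checking deletability against the current image before each
# removal, and never deleting a pixel that is strictly higher than every
# remaining neighbour.  Erosion therefore consumes the lower flank of the
# ridge first and the surviving line settles on the height maximum; on a
# constant-height ridge no pixel is protected and the erosion stays
# symmetric, reproducing the classic medial result.
zhang_suen <- function(Bp, Hp, height_bias) {
  nr <- nrow(Bp)
  # neighbour linear-index offsets in Zhang-Suen order P2..P9 (N, NE, E, SE,
  # S, SW, W, NW); rows increase downwards, columns rightwards
  off <- c(-1L, nr - 1L, nr, nr + 1L, 1L, -nr + 1L, -nr, -nr - 1L)
  if (!height_bias) {
    repeat {
      changed <- FALSE
      for (sub in 1:2) {
        idx <- which(Bp)
        if (!length(idx)) break
        cnd <- zs_conditions(Bp, idx, off, sub)
        if (any(cnd)) {
          Bp[idx[cnd]] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    return(Bp)
  }
  repeat {
    idx <- which(Bp)
    if (!length(idx)) break
    cnd <- zs_conditions(Bp, idx, off, 1L) | zs_conditions(Bp, idx, off, 2L)
    cand <- idx[cnd]
    if (!length(cand)) break
    # spare the highest candidate tier this iteration so the erosion
    # consumes lower flanks first and the crest survives; when all
    # candidates share one height there is nothing to bias and one classic
    # simultaneous iteration keeps the erosion symmetric
    h <- Hp[cand]
    spare <- h >= max(h) - 1e-12
    if (all(spare)) {
      changed <- FALSE
      for (sub in 1:2) {
        idx2 <- which(Bp)
        cnd2 <- zs_conditions(Bp, idx2, off, sub)
        if (any(cnd2)) {
          Bp[idx2[cnd2]] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
      next
    }
    cand <- cand[!spare]
    cand <- cand[order(Hp[cand], cand)]
    changed <- FALSE
    for (p in cand) {
      nb <- Bp[p + off]
      s <- sum(nb)
      if (s < 2L || s > 6L) next
      if (sum(!nb & nb[c(2:8, 1L)]) != 1L) next
      ok1 <- !(nb[1] && nb[3] && nb[5]) && !(nb[3] && nb[5] && nb[7])
      ok2 <- !(nb[1] && nb[3] && nb[7]) && !(nb[1] && nb[5] && nb[7])
      if (!ok1 && !ok2) next
      Bp[p] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  Bp
}

zs_conditions <- function(Bp, idx, off, sub) {
  nb <- matrix(FALSE, length(idx), 8L)
  for (k in 1:8) nb[, k] <- Bp[idx + off[k]]
  Bcnt <- rowSums(nb)
  nxt <- nb[, c(2:8, 1L), drop = FALSE]
  A <- rowSums((!nb) & nxt)
  if (sub == 1L) {
    Bcnt >= 2 & Bcnt <= 6 & A == 1 &
      !(nb[, 1] & nb[, 3] & nb[, 5]) & !(nb[, 3] & nb[, 5] & nb[, 7])
  } else {
    Bcnt >= 2 & Bcnt <= 6 & A == 1 &
      !(nb[, 1] & nb[, 3] & nb[, 7]) & !(nb[, 1] & nb[, 5] & nb[, 7])
  }
}

# remove redundant corner pixels left by thinning: a pixel with >= 2
# neighbours whose neighbours stay mutually 8-connected without it is a
# staircase duplicate
remove_staircase <- function(Bp) {
  nr <- nrow(Bp)
  off <- c(-1L, nr - 1L, nr, nr + 1L, 1L, -nr + 1L, -nr, -nr - 1L)
  # ring adjacency between neighbour slots (positions on the 3x3 ring)
  pos <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  ring_adj <- matrix(FALSE, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    ring_adj[i, j] <- i != j && max(abs(pos[i, ] - pos[j, ])) <= 1L
  }
  repeat {
    changed <- FALSE
    for (p in which(Bp)) {
      nb <- Bp[p + off]
      s <- sum(nb)
      if (s < 2L) next
      ids <- which(nb)
      # connected components of the occupied ring cells
      comp <- seq_along(ids)
      repeat {
        merged <- FALSE
        for (i in seq_along(ids)) for (j in seq_along(ids)) {
          if (comp[i] != comp[j] && ring_adj[ids[i], ids[j]]) {
            comp[comp == comp[j]] <- comp[i]
            merged <- TRUE
          }
        }
        if (!merged) break
      }
      if (length(unique(comp)) == 1L) {
        Bp[p] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  Bp
}

#' Pixel degrees of a skeleton
#'
#' @param sk an `afm_skeleton`.
#' @return integer vector, the number of 8-neighbours of each skeleton pixel
#'   (2 on the backbone, 1 at endpoints, 3+ at junctions and crossings).
#' @export
skeleton_degree <- function(sk) {
  m <- skeleton_matrix(sk)
  nr <- nrow(m); nc <- ncol(m)
  mp <- matrix(FALSE, nr + 2L, nc + 2L)
  mp[2:(nr + 1L), 2:(nc + 1L)] <- m
  npr <- nr + 2L
  off <- c(-1L, npr - 1L, npr, npr + 1L, 1L, -npr + 1L, -npr, -npr - 1L)
  idx <- (sk$col + 1L) * npr + (sk$row + 1L) + 1L
  deg <- integer(length(idx))
  for (k in 1:8) deg <- deg + mp[idx + off[k]]
  deg
}
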