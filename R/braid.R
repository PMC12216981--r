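#' Closed 3D curve from a braid word
#'
#' Builds a polyline embedding of the closure of a braid.  Strands run along
#' the y axis at unit x spacing; each braid letter exchanges two neighbouring
#' strands with a smooth cosine swap, lifting the over strand to positive z
#' (for a positive letter, the strand moving from column `i` to `i + 1`
#' passes over).  Closure arcs return each strand to the top around the left
#' side in the z = 0 plane, nested so they add no crossings.  Used to build
#' reference diagrams (e.g. twist knots) and renderable synthetic molecules.
#'
#' @param word integer vector; `i` stands for the positive generator swapping
#'   strands `i` and `i+1`, `-i` for its inverse.
#' @param n_strands number of strands; defaults to `max(abs(word)) + 1`.
#' @param samples_per_swap polyline samples across one crossing.
#' @param z_height z amplitude of the over/under separation.
#' @return list of closed polylines (n x 3 matrices), one per link component.
#' @export
braid_closure_curve <- function(word, n_strands = max(abs(word)) + 1L,
                                samples_per_swap = 13L, z_height = 0.35) {
  stopifnot(length(word) >= 1L, all(abs(word) >= 1L),
            all(abs(word) < n_strands))
  m <- n_strands
  L <- length(word)
  # paths[[s]]: polyline of the strand that starts at the top of column s
  paths <- lapply(seq_len(m), function(s) matrix(c(s, 0, 0), ncol = 3))
  col_of <- seq_len(m)            # current column -> starting strand
  for (step in seq_len(L)) {
    i <- abs(word[step]); pos <- word[step] > 0
    y0 <- step - 1; y1 <- step
    for (cc in seq_len(m)) {
      s <- col_of[cc]
      if (cc != i && cc != i + 1L) {
        paths[[s]] <- rbind(paths[[s]], c(cc, y1, 0))
      }
    }
    sa <- col_of[i]; sb <- col_of[i + 1L]
    tau <- seq(0, 1, length.out = samples_per_swap)[-1]
    xa <- i + (1 - cos(pi * tau)) / 2      # column i -> i+1
    xb <- i + 1L - (1 - cos(pi * tau)) / 2 # column i+1 -> i
    bump <- sin(pi * tau) * z_height
    # positive letter: the strand moving right (a) passes over
    za <- if (pos) bump else -bump
    paths[[sa]] <- rbind(paths[[sa]], cbind(xa, y0 + tau, za))
    paths[[sb]] <- rbind(paths[[sb]], cbind(xb, y0 + tau, -za))
    col_of[c(i, i + 1L)] <- c(sb, sa)
  }
  # closure arcs: bottom of column c back to top of column c, around the left
  closure_arc <- function(cc) {
    off <- 0.45 * cc
    xl <- 0.4 - off - 0.45
    rbind(c(cc, L + off, 0),
          c(xl, L + off, 0),
          c(xl, -off, 0),
          c(cc, -off, 0))
  }
  comps <- list()
  done <- logical(m)
  for (start in seq_len(m)) {
    if (done[start]) next
    comp <- NULL
    cur <- start
    repeat {
      done[cur] <- TRUE
      p <- paths[[cur]]
      end_col <- round(p[nrow(p), 1])
      comp <- rbind(comp, p, closure_arc(end_col))
      cur <- end_col
      if (cur == start) break
    }
    # drop consecutive duplicates
    keep <- c(TRUE, rowSums(abs(diff(comp))) > 1e-9)
    comp <- comp[keep, , drop = FALSE]
    if (sum(abs(comp[1, ] - comp[nrow(comp), ])) < 1e-9) {
      comp <- comp[-nrow(comp), , drop = FALSE]
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Closed 3D curve from a 4-plat (2-bridge) word
#'
#' Builds the plat closure of a 4-strand braid word: strand pairs (1,2) and
#' (3,4) are capped by arcs at top and bottom.  Rational (2-bridge) knots and
#' links, including the twist-knot family C(k, 2), arise this way.
#'
#' @inheritParams braid_closure_curve
#' @return list of closed polylines (n x 3 matrices).
#' @export
plat_closure_curve <- function(word, samples_per_swap = 13L, z_height = 0.35) {
  m <- 4L
  stopifnot(all(abs(word) >= 1L), all(abs(word) < m))
  L <- length(word)
  paths <- lapply(seq_len(m), function(s) matrix(c(s, 0, 0), ncol = 3))
  col_of <- seq_len(m)
  for (step in seq_len(L)) {
    i <- abs(word[step]); pos <- word[step] > 0
    y0 <- step - 1; y1 <- step
    for (cc in seq_len(m)) {
      s <- col_of[cc]
      if (cc != i && cc != i + 1L) paths[[s]] <- rbind(paths[[s]], c(cc, y1, 0))
    }
    sa <- col_of[i]; sb <- col_of[i + 1L]
    tau <- seq(0, 1, length.out = samples_per_swap)[-1]
    xa <- i + (1 - cos(pi * tau)) / 2
    xb <- i + 1L - (1 - cos(pi * tau)) / 2
    bump <- sin(pi * tau) * z_height
    za <- if (pos) bump else -bump
    paths[[sa]] <- rbind(paths[[sa]], cbind(xa, y0 + tau, za))
    paths[[sb]] <- rbind(paths[[sb]], cbind(xb, y0 + tau, -za))
    col_of[c(i, i + 1L)] <- c(sb, sa)
  }
  cap <- function(c1, c2, y, up) {
    th <- seq(0, pi, length.out = 17L)[-c(1L, 17L)]
    mid <- (c1 + c2) / 2; r <- abs(c2 - c1) / 2
    cbind(mid - r * cos(th) * sign(c2 - c1), y + (if (up) -r else r) * sin(th), 0)
  }
  # stitch strands and caps into closed components
  strand_top <- seq_len(m)                         # strand s starts at column s
  strand_bot <- integer(m); strand_bot[col_of] <- seq_len(m)
  partner <- c(2L, 1L, 4L, 3L)
  comps <- list()
  used <- logical(m)
  for (s0 in seq_len(m)) {
    if (used[s0]) next
    comp <- NULL
    s <- s0
    repeat {
      used[s] <- TRUE
      comp <- rbind(comp, paths[[s]])                     # top col -> bottom col
      bc <- round(paths[[s]][nrow(paths[[s]]), 1])
      comp <- rbind(comp, cap(bc, partner[bc], L, up = FALSE))
      s_next <- col_of[partner[bc]]                       # strand ending at partner col
      used[s_next] <- TRUE
      comp <- rbind(comp, paths[[s_next]][rev(seq_len(nrow(paths[[s_next]]))), , drop = FALSE])
      tc <- s_next                                        # its top column
      comp <- rbind(comp, cap(tc, partner[tc], 0, up = TRUE))
      s <- partner[tc]
      if (s == s0) break
    }
    keep <- c(TRUE, rowSums(abs(diff(comp))) > 1e-9)
    comp <- comp[keep, , drop = FALSE]
    if (sum(abs(comp[1, ] - comp[nrow(comp), ])) < 1e-9) {
      comp <- comp[-nrow(comp), , drop = FALSE]
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}
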