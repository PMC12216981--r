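#' Planar knot/link diagrams with crossing order
#'
#' A crossing diagram records, for each closed component, the cyclic sequence
#' of crossing passages (which crossing, and whether the strand passes over or
#' under) together with a sign per crossing.  The sign follows the usual
#' convention: `+1` when the 2D cross product of the over-strand tangent with
#' the under-strand tangent is positive (right-handed crossing).  Components
#' without any passages are retained as crossing-free loops, so unlinked
#' circles stay visible to the classifier.
#'
#' @param components list; each element a data frame with integer column
#'   `crossing` and logical column `over`, giving the cyclic passage sequence
#'   of one closed component.  Zero-row components are free loops.
#' @param signs named integer vector (`+1`/`-1`), names are crossing ids.
#' @return an object of class `knot_diagram`.
#' @examples
#' # a single positive curl (Reidemeister I kink) on an unknot
#' d <- knot_diagram(
#'   list(data.frame(crossing = c(1L, 1L), over = c(TRUE, FALSE))),
#'   c(`1` = 1L)
#' )
#' n_crossings(d)
#' @export
knot_diagram <- function(components, signs) {
  components <- lapply(components, function(co) {
    co <- as.data.frame(co)
    stopifnot(all(c("crossing", "over") %in% names(co)))
    data.frame(crossing = as.integer(co$crossing), over = as.logical(co$over))
  })
  signs <- stats::setNames(as.integer(signs), names(signs))
  all_pass <- do.call(rbind, c(components, list(data.frame(crossing = integer(), over = logical()))))
  ids <- sort(unique(all_pass$crossing))
  for (id in ids) {
    ov <- all_pass$over[all_pass$crossing == id]
    if (length(ov) != 2L || sum(ov) != 1L) {
      stop("crossing ", id, " must be passed exactly twice, once over and once under")
    }
  }
  if (!all(as.character(ids) %in% names(signs))) {
    stop("every crossing needs a sign")
  }
  if (length(ids) && !all(abs(signs[as.character(ids)]) == 1L)) {
    stop("crossing signs must be +1 or -1")
  }
  structure(list(components = components,
                 signs = if (length(ids)) signs[as.character(ids)] else
                   stats::setNames(integer(0), character(0))),
            class = "knot_diagram")
}

#' @rdname knot_diagram
#' @param diag a `knot_diagram`.
#' @export
n_crossings <- function(diag) length(diag$signs)

#' @rdname knot_diagram
#' @export
n_components <- function(diag) length(diag$components)

#' @export
print.knot_diagram <- function(x, ...) {
  cat("<knot_diagram> ", n_components(x), " component(s), ",
      n_crossings(x), " crossing(s)", sep = "")
  if (n_crossings(x)) {
    cat("; signs: ", paste0(ifelse(x$signs > 0, "+", "-"), collapse = ""), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Invert the crossing order at one crossing
#'
#' Swaps which strand passes over at the given crossing.  Exchanging over and
#' under reverses the handedness of the crossing, so its sign is negated.
#'
#' @param diag a `knot_diagram`.
#' @param id crossing id.
#' @return the modified diagram.
#' @export
flip_crossing <- function(diag, id) {
  id <- as.integer(id)
  if (!as.character(id) %in% names(diag$signs)) stop("no crossing with id ", id)
  diag$components <- lapply(diag$components, function(co) {
    hit <- co$crossing == id
    co$over[hit] <- !co$over[hit]
    co
  })
  diag$signs[as.character(id)] <- -diag$signs[as.character(id)]
  diag
}

#' Mirror image of a diagram (all crossings inverted)
#' @param diag a `knot_diagram`.
#' @export
mirror_diagram <- function(diag) {
  for (id in names(diag$signs)) diag <- flip_crossing(diag, as.integer(id))
  diag
}

#' Reverse the orientation of one component
#'
#' Over/under assignments are orientation-independent; crossing signs flip for
#' crossings in which exactly one of the two passages belongs to the reversed
#' component.
#' @keywords internal
reverse_component <- function(diag, j) {
  co <- diag$components[[j]]
  cnt_in_j <- table(factor(co$crossing, levels = names(diag$signs)))
  diag$components[[j]] <- co[rev(seq_len(nrow(co))), , drop = FALSE]
  rownames(diag$components[[j]]) <- NULL
  flip <- names(cnt_in_j)[cnt_in_j == 1L]
  diag$signs[flip] <- -diag$signs[flip]
  diag
}

# all orientation variants obtained by reversing subsets of components 2..k
orientation_variants <- function(diag) {
  k <- n_components(diag)
  if (k <= 1L) return(list(diag))
  out <- list()
  for (mask in 0:(2^(k - 1L) - 1L)) {
    d <- diag
    for (j in 2:k) if (bitwAnd(mask, bitwShiftL(1L, j - 2L)) != 0L) {
      d <- reverse_component(d, j)
    }
    out[[length(out) + 1L]] <- d
  }
  out
}

#' PD (planar diagram) code of a crossing diagram
#'
#' Arcs are numbered consecutively along each component; each crossing is a
#' row of four arc labels listed counter-clockwise starting from the incoming
#' under-strand arc.
#'
#' @param diag a `knot_diagram`.
#' @return integer matrix with one row per crossing and columns `e1..e4`,
#'   plus attribute `n_free_loops`.
#' @export
pd_code <- function(diag) {
  comps <- diag$components
  n <- n_crossings(diag)
  arc <- 0L
  # per passage: incoming and outgoing arc labels
  inc <- list(); out <- list()
  for (i in seq_along(comps)) {
    k <- nrow(comps[[i]])
    if (k == 0L) { inc[[i]] <- integer(0); out[[i]] <- integer(0); next }
    arcs <- arc + seq_len(k)
    arc <- arc + k
    out[[i]] <- arcs
    inc[[i]] <- c(arcs[k], arcs[-k])
  }
  pd <- matrix(NA_integer_, nrow = n, ncol = 4,
               dimnames = list(names(diag$signs), paste0("e", 1:4)))
  for (id in names(diag$signs)) {
    iu <- ou <- io <- oo <- NA_integer_
    for (i in seq_along(comps)) {
      co <- comps[[i]]
      hit <- which(co$crossing == as.integer(id))
      for (j in hit) {
        if (co$over[j]) { io <- inc[[i]][j]; oo <- out[[i]][j] }
        else            { iu <- inc[[i]][j]; ou <- out[[i]][j] }
      }
    }
    pd[id, ] <- if (diag$signs[id] > 0L) c(iu, oo, ou, io) else c(iu, io, ou, oo)
  }
  attr(pd, "n_arcs") <- arc
  attr(pd, "n_free_loops") <- sum(vapply(comps, nrow, 0L) == 0L)
  pd
}

#' Gauss code of a diagram
#'
#' One character string per component: `O`/`U` for over/under passages with
#' the crossing id and its sign.
#' @param diag a `knot_diagram`.
#' @export
gauss_code <- function(diag) {
  vapply(diag$components, function(co) {
    if (nrow(co) == 0L) return("")
    paste0(ifelse(co$over, "O", "U"), co$crossing,
           ifelse(diag$signs[as.character(co$crossing)] > 0, "+", "-"),
           collapse = " ")
  }, "")
}

#' Simplify a diagram by Reidemeister I and II moves
#'
#' Removes curls (a crossing whose two passages are consecutive along one
#' component) and cancelling crossing pairs (two crossings joined by two
#' parallel arcs with one strand passing over at both), repeating until no
#' further move applies.  Both moves preserve the topology, so the Jones
#' polynomial of the simplified diagram equals that of the input.
#'
#' @param diag a `knot_diagram`.
#' @return the reduced `knot_diagram`.
#' @export
simplify_diagram <- function(diag) {
  repeat {
    res <- simplify_once(diag)
    if (is.null(res)) return(diag)
    diag <- res
  }
}

simplify_once <- function(diag) {
  comps <- diag$components
  # Reidemeister I
  for (i in seq_along(comps)) {
    co <- comps[[i]]
    k <- nrow(co)
    if (k < 2L) next
    nxt <- c(2:k, 1L)[seq_len(k)]
    for (j in seq_len(k)) {
      if (co$crossing[j] == co$crossing[nxt[j]] && j != nxt[j]) {
        return(drop_crossings(diag, co$crossing[j]))
      }
      if (k == 2L) break  # both cyclic neighbours are the same pair
    }
  }
  # Reidemeister II: consecutive passages at crossings c,d with equal roles,
  # whose partner passages are also consecutive with the complementary role.
  loc <- passage_index(diag)
  for (i in seq_along(comps)) {
    co <- comps[[i]]
    k <- nrow(co)
    if (k < 2L) next
    for (j in seq_len(k)) {
      j2 <- if (j == k) 1L else j + 1L
      if (j2 == j) next
      c1 <- co$crossing[j]; c2 <- co$crossing[j2]
      if (c1 == c2) next
      if (co$over[j] != co$over[j2]) next
      p1 <- other_passage(loc, c1, i, j)
      p2 <- other_passage(loc, c2, i, j2)
      if (is.null(p1) || is.null(p2)) next
      if (p1[1] != p2[1]) next               # partners on the same component
      kk <- nrow(comps[[p1[1]]])
      adj <- (p2[2] %% kk) + 1L == p1[2] || (p1[2] %% kk) + 1L == p2[2]
      if (!adj) next
      # distinctness of the four passages
      if (p1[1] == i && (p1[2] %in% c(j, j2))) next
      if (p2[1] == i && (p2[2] %in% c(j, j2))) next
      return(drop_crossings(diag, c(c1, c2)))
    }
  }
  NULL
}

passage_index <- function(diag) {
  idx <- list()
  for (i in seq_along(diag$components)) {
    co <- diag$components[[i]]
    for (j in seq_len(nrow(co))) {
      key <- as.character(co$crossing[j])
      idx[[key]] <- rbind(idx[[key]], c(i, j))
    }
  }
  idx
}

other_passage <- function(loc, crossing, i, j) {
  m <- loc[[as.character(crossing)]]
  for (r in seq_len(nrow(m))) {
    if (!(m[r, 1] == i && m[r, 2] == j)) return(m[r, ])
  }
  NULL
}

drop_crossings <- function(diag, ids) {
  comps <- lapply(diag$components, function(co) {
    co <- co[!co$crossing %in% ids, , drop = FALSE]
    rownames(co) <- NULL
    co
  })
  signs <- diag$signs[!names(diag$signs) %in% as.character(ids)]
  structure(list(components = comps, signs = signs), class = "knot_diagram")
}

#' Total writhe (sum of crossing signs) of a diagram
#' @param diag a `knot_diagram`.
#' @export
diagram_writhe <- function(diag) if (n_crossings(diag)) sum(diag$signs) else 0L
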