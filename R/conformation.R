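#' Conformation rule table
#'
#' Deposition conformation classes are assigned from the number of crossing
#' nodes and the branch count per node, before (and independently of) any
#' topological tracing — the classes exist precisely because heavily
#' clustered molecules cannot be traced.  The shipped defaults are a
#' documented heuristic, editable here:
#' \itemize{
#'   \item `bow-tie`: a single node with at least `bowtie_min_branches`
#'     branches (all crossings collapsed into one point between two lobes);
#'   \item `clustered`: any node with at least `clustered_min_branches`
#'     branches;
#'   \item `open`: `open_n_nodes` nodes, all 4-branched, pairwise separated
#'     by more than the node merge distance;
#'   \item `taut`: 2–3 nodes with >= 4 branches lying close to a common
#'     line (within `taut_collinear_tol` of the node span);
#'   \item otherwise `unclassified`.
#' }
#'
#' @param open_n_nodes node count of the open catenane conformation.
#' @param clustered_min_branches branch count that marks a clustered node.
#' @param bowtie_min_branches branch count of the single bow-tie node.
#' @param taut_collinear_tol perpendicular tolerance (fraction of span).
#' @param min_separation_nm minimum pairwise node separation for `open`.
#' @return a list of class `conformation_rules`.
#' @export
conformation_rules <- function(open_n_nodes = 4L,
                               clustered_min_branches = 6L,
                               bowtie_min_branches = 8L,
                               taut_collinear_tol = 0.25,
                               min_separation_nm = 7) {
  structure(list(open_n_nodes = as.integer(open_n_nodes),
                 clustered_min_branches = as.integer(clustered_min_branches),
                 bowtie_min_branches = as.integer(bowtie_min_branches),
                 taut_collinear_tol = taut_collinear_tol,
                 min_separation_nm = min_separation_nm),
            class = "conformation_rules")
}

#' Classify the deposition conformation of an object
#'
#' @param nodes list of `crossing_node`s (merged) for the object.
#' @param pixel_size_nm nm per pixel (for node separations).
#' @param rules a [conformation_rules()] table.
#' @return one of `"open"`, `"taut"`, `"clustered"`, `"bow-tie"`,
#'   `"unclassified"`.
#' @export
classify_conformation <- function(nodes, pixel_size_nm = 1,
                                  rules = conformation_rules()) {
  nb <- vapply(nodes, function(nd) nd$n_branches, 0L)
  n <- length(nodes)
  if (n == 1L && nb[1] >= rules$bowtie_min_branches) return("bow-tie")
  if (any(nb >= rules$clustered_min_branches)) return("clustered")
  cent <- if (n) t(vapply(nodes, function(nd) nd$centroid, c(0, 0))) else
    matrix(numeric(0), ncol = 2)
  if (n == rules$open_n_nodes && all(nb == 4L)) {
    d <- stats::dist(cent * pixel_size_nm)
    if (all(d > rules$min_separation_nm)) return("open")
  }
  if (n >= 2L && n <= 3L && all(nb >= 4L)) {
    if (n == 2L || collinearity(cent) <= rules$taut_collinear_tol) {
      return("taut")
    }
  }
  "unclassified"
}

# max perpendicular deviation of points from the line through the two most
# distant points, as a fraction of that span
collinearity <- function(pts) {
  d <- as.matrix(stats::dist(pts))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  a <- pts[ij[1], ]; b <- pts[ij[2], ]
  span <- sqrt(sum((b - a)^2))
  if (span < 1e-9) return(0)
  e <- (b - a) / span
  perp <- abs((sweep(pts, 2, a) %*% c(-e[2], e[1])))
  max(perp) / span
}
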