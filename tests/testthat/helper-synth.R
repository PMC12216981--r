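# Shared rendered fixtures, built once per test run.  Renders are a second
# or so each, so tests that only inspect different aspects of the same
# object reuse these.

.fixtures <- new.env(parent = emptyenv())

fixture_render <- function(topology, seed = 1L, ...) {
  key <- paste(topology, seed, paste(deparse(substitute(list(...))), collapse = ""))
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  sp <- synth_spec(topology, seed = seed, ...)
  gt <- make_curve(sp)
  r <- render_pseudo_afm(gt, sp)
  out <- list(spec = sp, gt = gt, heightmap = r$heightmap, truth = r$truth)
  .fixtures[[key]] <- out
  out
}

fixture_skeleton <- function(fx) {
  key <- paste0("sk_", fx$heightmap$source_id)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  flat <- flatten(fx$heightmap)
  mask <- mask_grains(flat, mask_config(threshold_nm = 0.6, min_area_px = 60))
  sk <- prune_skeleton(skeletonize_height_biased(mask, flat, 1L))
  out <- list(flat = flat, mask = mask, sk = sk)
  .fixtures[[key]] <- out
  out
}

# build a heightmap directly from a logical stencil at a given ridge height
stencil_heightmap <- function(stencil, height = 2, pixel_size_nm = 1) {
  heightmap(stencil * height, pixel_size_nm, "stencil")
}

# skeleton tibble from explicit 0-based pixel coordinates; rasterised paths
# can contain staircase duplicates, so the standard cleanup is applied
skeleton_from_coords <- function(coords, heights = 2, dim = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim)) dim <- c(max(coords[, 1]) + 3L, max(coords[, 2]) + 3L)
  if (length(heights) == 1L) heights <- rep(heights, nrow(coords))
  ord <- order(coords[, 1], coords[, 2])
  sk <- topotrace:::new_skeleton(
    tibble::tibble(row = as.integer(coords[ord, 1]),
                   col = as.integer(coords[ord, 2]),
                   height_nm = heights[ord]),
    dim = dim, pixel_size_nm = 1, grain = 1L
  )
  m <- topotrace:::skeleton_matrix(sk)
  mp <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  mp[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  mp <- topotrace:::remove_staircase(mp)
  keep <- mp[cbind(sk$row + 2L, sk$col + 2L)]
  topotrace:::new_skeleton(sk[keep, ], dim = dim, pixel_size_nm = 1, grain = 1L)
}

# pixel path helpers for constructing synthetic skeletons
px_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0))
  cbind(round(seq(r0, r1, length.out = n + 1L)),
        round(seq(c0, c1, length.out = n + 1L)))
}

px_circle <- function(r_centre, c_centre, radius) {
  th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * radius * 2))
  pts <- unique(cbind(round(r_centre + radius * sin(th)),
                      round(c_centre + radius * cos(th))))
  pts
}
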