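#' Render a ground-truthed pseudo-AFM image
#'
#' Converts a 3D curve set into a synthetic AFM topograph the way deposited
#' DNA appears to the instrument: the curve is projected onto the XY plane
#' and rasterised as a ridge of `ridge_height_nm`; at each crossing the over
#' strand is kept continuous and raised toward twice the duplex height (its
#' apex reduced by `crossing_compression`, so compression 1 flattens the
#' crossing to single-duplex height and destroys the crossing-order signal);
#' the image is then dilated by the tip radius (grey-scale max filter with a
#' disc, emulating tip convolution), Gaussian-smoothed, and Gaussian pixel
#' noise is added.  Placement jitter and noise derive solely from
#' `spec$seed`, so a spec renders reproducibly.
#'
#' @param gt a `ground_truth` from [make_curve()].
#' @param spec the [synth_spec()] used (defaults to `gt$spec`).
#' @return a list: `heightmap` (an `afm_heightmap`), and `truth` — the
#'   ground truth with crossing positions mapped to pixel coordinates.
#' @export
render_pseudo_afm <- function(gt, spec = gt$spec) {
  ps <- spec$pixel_size_nm
  margin_nm <- 3 * spec$tip_radius_nm + 8
  comps_nm <- c(gt$curves, gt$open_curves)
  closed_flags <- c(rep(TRUE, length(gt$curves)),
                    rep(FALSE, length(gt$open_curves %||% list())))
  with_seed(spec$seed, {
    th <- stats::runif(1, 0, 2 * pi)
    jit <- stats::runif(2, -0.5, 0.5) * ps
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    comps_nm <- lapply(comps_nm, function(m) {
      xy <- m[, 1:2] %*% rot
      cbind(xy[, 1] + jit[1], xy[, 2] + jit[2], m[, 3])
    })
    ext <- do.call(rbind, lapply(comps_nm, function(m) m[, 1:2]))
    lo <- apply(ext, 2, min) - margin_nm
    hi <- apply(ext, 2, max) + margin_nm
    npx <- ceiling((hi - lo) / ps)
    # resample finely in pixel units
    comps_px <- lapply(seq_along(comps_nm), function(i) {
      m <- comps_nm[[i]]
      xy <- sweep(m[, 1:2], 2, lo) / ps
      resample_polyline(cbind(xy, m[, 3]), 0.4, closed = closed_flags[i])
    })
    # crossings of the rendered projection, over strand from true z
    cross <- polyline_crossings(lapply(comps_px, function(m)
      m[, 1:2, drop = FALSE]))
    H <- matrix(0, npx[2], npx[1])   # rows = y, cols = x
    sigma_cross_px <- max(spec$tip_radius_nm, 3) / ps
    core_px <- max(spec$duplex_width_nm / 2 / ps, 0.8)
    for (i in seq_along(comps_px)) {
      m <- comps_px[[i]]
      elev <- rep(0, nrow(m))
      if (nrow(cross)) {
        for (k in seq_len(nrow(cross))) {
          za <- interp_z(comps_px, cross$comp_a[k], cross$seg_a[k], cross$t_a[k],
                         closed_flags)
          zb <- interp_z(comps_px, cross$comp_b[k], cross$seg_b[k], cross$t_b[k],
                         closed_flags)
          over_a <- za >= zb
          oc <- if (over_a) cross$comp_a[k] else cross$comp_b[k]
          if (oc != i) next
          s0 <- if (over_a) cross$s_a[k] else cross$s_b[k]
          ds_px <- arc_dist(seq_len(nrow(m)), s0, nrow(m), closed_flags[i])
          elev <- pmax(elev, exp(-ds_px^2 / (2 * sigma_cross_px^2)))
        }
      }
      hts <- spec$ridge_height_nm *
        (1 + (1 - spec$crossing_compression) * elev)
      H <- stamp_ridge(H, m[, 1:2], hts, core_px)
    }
    if (spec$tip_radius_nm > 0) {
      H <- grey_dilate_disc(H, spec$tip_radius_nm / ps)
    }
    H <- gaussian_blur(H, 1.0)
    if (spec$noise_sd_nm > 0) {
      H <- H + matrix(stats::rnorm(length(H), 0, spec$noise_sd_nm),
                      nrow(H), ncol(H))
    }
    truth <- gt
    truth$comps_px <- comps_px
    truth$closed_flags <- closed_flags
    if (nrow(cross)) {
      truth$crossings_px <- data.frame(x = cross$x, y = cross$y)
    } else {
      truth$crossings_px <- data.frame(x = numeric(), y = numeric())
    }
    list(heightmap = heightmap(H, ps,
                               paste0("synthetic:", spec$topology,
                                      ":seed", spec$seed)),
         truth = truth)
  })
}

interp_z <- function(comps, ci, si, t, closed_flags) {
  m <- comps[[ci]]
  n <- nrow(m)
  j2 <- if (si == n) 1L else si + 1L
  (1 - t) * m[si, 3] + t * m[j2, 3]
}

arc_dist <- function(idx, s0, n, closed) {
  d <- abs(idx - s0)
  if (closed) d <- pmin(d, n - d)
  d * 0.4   # sample spacing in px
}

resample_polyline <- function(m, spacing, closed = TRUE) {
  pts <- if (closed) rbind(m, m[1, ]) else m
  seg <- sqrt(rowSums(diff(pts[, 1:2, drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  ns <- max(8L, ceiling(total / spacing))
  sq <- seq(0, total, length.out = ns + 1L)
  if (closed) sq <- sq[-(ns + 1L)]
  out <- matrix(0, length(sq), ncol(m))
  for (j in seq_len(ncol(m))) {
    out[, j] <- stats::approx(s, pts[, j], xout = sq, rule = 2)$y
  }
  out
}

# deposit ridge height by max-combining circular caps at each sample point
stamp_ridge <- function(H, xy, hts, radius_px) {
  nr <- nrow(H); nc <- ncol(H)
  r <- ceiling(radius_px + 0.5)
  win <- expand.grid(dr = -r:r, dc = -r:r)
  for (i in seq_len(nrow(xy))) {
    cx <- xy[i, 1]; cy <- xy[i, 2]
    c0 <- round(cx) + 1L; r0 <- round(cy) + 1L
    rr <- r0 + win$dr; cc <- c0 + win$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!any(ok)) next
    d2 <- ((cc[ok] - 1L) - cx)^2 + ((rr[ok] - 1L) - cy)^2
    prof <- 1 - d2 / (radius_px + 0.5)^2
    keep <- prof > 0
    if (!any(keep)) next
    lin <- (cc[ok][keep] - 1L) * nr + rr[ok][keep]
    vals <- hts[i] * sqrt(prof[keep])
    cur <- H[lin]
    upd <- vals > cur
    if (any(upd)) H[lin[upd]] <- vals[upd]
  }
  H
}

# grey-scale dilation with a disc structuring element (max filter)
grey_dilate_disc <- function(H, radius_px) {
  r <- floor(radius_px + 1e-9)
  if (r < 1L) return(H)
  nr <- nrow(H); nc <- ncol(H)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius_px^2 + 1e-9, ]
  out <- H
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    if (dr == 0L && dc == 0L) next
    src_r <- max(1L, 1L - dr):min(nr, nr - dr)
    src_c <- max(1L, 1L - dc):min(nc, nc - dc)
    out[src_r + dr, src_c + dc] <-
      pmax(out[src_r + dr, src_c + dc], H[src_r, src_c])
  }
  out
}

# run code with a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Deterministic synthetic fixture suite
#'
#' Generates a ground-truthed set of pseudo-AFM renders spanning the
#' supported topologies under several imaging conditions (`clean`: no noise,
#' no crossing compression; `noisy`; `compressed`; `clustered`: a small
#' render whose crossings fall within the node merge distance).  The suite
#' is fully determined by `seed`.
#'
#' @param seed integer master seed.
#' @param topologies character vector of topology names (see [synth_spec()]).
#' @param conditions subset of `c("clean", "noisy", "compressed",
#'   "clustered")`.
#' @param dir optional directory: images are written as plain-text height
#'   grids plus a `manifest.csv`.
#' @return a tibble manifest with one row per render and a `specs` attribute
#'   (the list of `synth_spec`s).
#' @export
fixture_suite <- function(seed = 1L,
                          topologies = c("circle", "torus_knot3",
                                         "twist_knot4", "torus_knot5",
                                         "twist_knot5", "catenane_4node"),
                          conditions = c("clean", "noisy", "compressed",
                                         "clustered"),
                          dir = NULL) {
  rows <- list()
  specs <- list()
  salt <- 0L
  for (topo in topologies) {
    for (cond in conditions) {
      salt <- salt + 1L
      sp <- suite_spec(topo, cond, seed, salt)
      specs[[length(specs) + 1L]] <- sp
      rows[[length(rows) + 1L]] <- tibble::tibble(
        topology = topo, condition = cond, seed = sp$seed,
        length_nm = sp$length_nm, noise_sd_nm = sp$noise_sd_nm,
        crossing_compression = sp$crossing_compression,
        pixel_size_nm = sp$pixel_size_nm,
        file = paste0(topo, "_", cond, "_seed", sp$seed, ".csv")
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(manifest))) {
      gt <- make_curve(specs[[i]])
      r <- render_pseudo_afm(gt, specs[[i]])
      write_heightmap(r$heightmap, file.path(dir, manifest$file[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(manifest, "specs") <- specs
  manifest
}

suite_spec <- function(topo, cond, seed, salt = 0L) {
  base <- switch(topo,
    circle = list(topology = "circle", length_nm = 768),
    theta = list(topology = "theta", length_nm = 900),
    figure8_dimer = list(topology = "figure8_dimer", length_nm = 768),
    torus_knot3 = list(topology = "torus_knot", q = 3L, length_nm = 768),
    torus_knot5 = list(topology = "torus_knot", q = 5L, length_nm = 900),
    torus_knot7 = list(topology = "torus_knot", q = 7L, length_nm = 1100),
    twist_knot4 = list(topology = "twist_knot", n_crossings_target = 4L,
                       length_nm = 768),
    twist_knot5 = list(topology = "twist_knot", n_crossings_target = 5L,
                       length_nm = 900),
    catenane_4node = list(topology = "catenane_4node", length_nm = 561),
    stop("unknown suite topology: ", topo)
  )
  mods <- switch(cond,
    clean = list(noise_sd_nm = 0, crossing_compression = 0),
    noisy = list(noise_sd_nm = 0.15, crossing_compression = 0),
    compressed = list(noise_sd_nm = 0, crossing_compression = 0.9),
    clustered = list(noise_sd_nm = 0, crossing_compression = 0,
                     length_nm = base$length_nm / 3),
    stop("unknown condition: ", cond)
  )
  args <- utils::modifyList(base, mods)
  args$seed <- (seed * 97L + salt * 131L) %% .Machine$integer.max
  do.call(synth_spec, args)
}
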