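#' Specification for a synthetic pseudo-AFM molecule
#'
#' Collects the parameters that determine one ground-truthed synthetic
#' render: the topology and target contour length of the deposited molecule,
#' the imaging geometry (pixel size, tip radius), the ridge height of
#' tip-convolved DNA on mica, instrument noise, and how strongly crossings
#' are compressed toward single-duplex height (`crossing_compression` 0 keeps
#' the over strand fully raised; 1 flattens the crossing so the two duplex
#' profiles tie and the crossing order becomes unreadable).  The seed fully
#' determines the render.
#'
#' @param topology one of `"circle"`, `"theta"`, `"figure8_dimer"`,
#'   `"torus_knot"`, `"twist_knot"`, `"torus_link"`, `"catenane_4node"`.
#' @param length_nm target total contour length in nm (summed over
#'   components).
#' @param pixel_size_nm image calibration, nm per pixel.
#' @param tip_radius_nm AFM tip radius emulated by dilation.
#' @param ridge_height_nm apparent height of a single DNA duplex.
#' @param duplex_width_nm core ridge width before tip convolution.
#' @param noise_sd_nm standard deviation of additive Gaussian pixel noise.
#' @param crossing_compression in `[0, 1]`, see above.
#' @param p,q torus knot/link parameters (`p = 2` families).
#' @param n_crossings_target crossing number for `"twist_knot"` (3-7).
#' @param fork_stub_nm for `"theta"`: length of a short extra arm on one
#'   fork, turning it into a 4-way junction (a reversed replication fork);
#'   0 disables.
#' @param mirror render the mirror-image curve.
#' @param seed integer seed controlling placement jitter and noise.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(topology = c("circle", "theta", "figure8_dimer",
                                    "torus_knot", "twist_knot", "torus_link",
                                    "catenane_4node"),
                       length_nm = 600,
                       pixel_size_nm = 1,
                       tip_radius_nm = 5,
                       ridge_height_nm = 2,
                       duplex_width_nm = 2,
                       noise_sd_nm = 0,
                       crossing_compression = 0,
                       p = 2L, q = 3L,
                       n_crossings_target = 4L,
                       fork_stub_nm = 0,
                       mirror = FALSE,
                       seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(length_nm > 0, pixel_size_nm > 0, tip_radius_nm >= 0,
            ridge_height_nm > 0, noise_sd_nm >= 0,
            crossing_compression >= 0, crossing_compression <= 1)
  structure(list(topology = topology, length_nm = length_nm,
                 pixel_size_nm = pixel_size_nm, tip_radius_nm = tip_radius_nm,
                 ridge_height_nm = ridge_height_nm,
                 duplex_width_nm = duplex_width_nm,
                 noise_sd_nm = noise_sd_nm,
                 crossing_compression = crossing_compression,
                 p = as.integer(p), q = as.integer(q),
                 n_crossings_target = as.integer(n_crossings_target),
                 fork_stub_nm = fork_stub_nm,
                 mirror = isTRUE(mirror), seed = as.integer(seed)),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> ", x$topology, ", ", x$length_nm, " nm, ",
      x$pixel_size_nm, " nm/px, noise ", x$noise_sd_nm,
      " nm, compression ", x$crossing_compression, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
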