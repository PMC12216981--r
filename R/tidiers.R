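#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for classification results
#'
#' `tidy()` on a `topology_result` gives one row per crossing (sign and,
#' when available, the crossing-order reliability); `glance()` gives the
#' one-row summary (label, alternate label, minimum reliability, crossing
#' count).  `glance()` on a `pipeline_result` summarises a whole run.
#'
#' @param x a `topology_result` (or `pipeline_result` for
#'   `glance.pipeline_result`).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.topology_result <- function(x, ...) {
  n <- length(x$signs)
  tibble::tibble(
    crossing = seq_len(n),
    sign = if (n) as.integer(x$signs) else integer(0),
    cor = if (!is.null(x$cor) && length(x$cor) == n) as.numeric(x$cor)
          else rep(NA_real_, n)
  )
}

#' @rdname tidy.topology_result
#' @export
glance.topology_result <- function(x, ...) {
  tibble::tibble(
    rolfsen = x$rolfsen,
    family = x$family,
    chirality = x$chirality,
    alternate_rolfsen = x$alternate_rolfsen,
    min_cor = x$min_cor,
    n_crossings = x$n_crossings,
    writhe = if (length(x$signs)) sum(x$signs) else 0L,
    jones = if (is.null(x$polynomial)) NA_character_ else format(x$polynomial)
  )
}

#' Plot molecule traces over the height map
#'
#' Draws the flattened topograph with the ordered traces overlaid, colouring
#' crossing-region points by whether the strand passes over (lime) or under
#' (pink) — the display convention used for automated traces.
#'
#' @param object an `afm_traces` object.
#' @param hm optional `afm_heightmap` backdrop.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.afm_traces <- function(object, hm = NULL, ...) {
  nx <- to_nxyz(object)
  nx <- dplyr::group_by(nx, .data$molecule_id)
  nx <- dplyr::mutate(nx, zmax = max(.data$Z))
  nx <- dplyr::ungroup(nx)
  nx$pass <- dplyr::case_when(
    nx$Z == 0 ~ "backbone",
    nx$Z == nx$zmax ~ "over",
    TRUE ~ "under"
  )
  p <- ggplot2::ggplot()
  if (!is.null(hm)) {
    p <- p + ggplot2::geom_raster(
      data = heightmap_df(hm),
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$height_nm)) +
      ggplot2::scale_fill_gradient(low = "grey15", high = "grey85",
                                   name = "height (nm)")
  }
  p +
    ggplot2::geom_path(data = nx[nx$Z == 0, ],
                       ggplot2::aes(x = .data$X, y = .data$Y,
                                    group = .data$molecule_id),
                       colour = "#3366cc", linewidth = 0.4) +
    ggplot2::geom_point(data = nx[nx$Z > 0, ],
                        ggplot2::aes(x = .data$X, y = .data$Y,
                                     colour = .data$pass), size = 0.9) +
    ggplot2::scale_colour_manual(values = c(over = "#7fff00",
                                            under = "#ff69b4"),
                                 name = "crossing") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
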