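#' Calibrated AFM height maps
#'
#' An `afm_heightmap` is a rectangular grid of surface heights in nanometres
#' together with its (isotropic) pixel size.  Pixel coordinates are 0-based
#' `(row, col)` in row-major order; physical quantities are derived from
#' `pixel_size_nm` at computation time.
#'
#' @param heights numeric matrix of heights (nm); all values finite.
#' @param pixel_size_nm positive scalar, nm per pixel.
#' @param source_id free-text provenance tag.
#' @return an object of class `afm_heightmap`.
#' @export
heightmap <- function(heights, pixel_size_nm, source_id = "") {
  if (length(dim(heights)) != 2L || !is.numeric(heights)) {
    stop("heights must be a 2D numeric grid")
  }
  heights <- as.matrix(heights)
  if (!all(is.finite(heights))) stop("heights contain non-finite values")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("pixel_size_nm must be a positive number")
  }
  structure(list(heights = unname(heights),
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 source_id = as.character(source_id)),
            class = "afm_heightmap")
}

#' @export
print.afm_heightmap <- function(x, ...) {
  cat("<afm_heightmap> ", nrow(x$heights), " x ", ncol(x$heights), " px @ ",
      x$pixel_size_nm, " nm/px; height range [",
      round(min(x$heights), 3), ", ", round(max(x$heights), 3), "] nm",
      if (nzchar(x$source_id)) paste0("; ", x$source_id), "\n", sep = "")
  invisible(x)
}

#' @export
dim.afm_heightmap <- function(x) dim(x$heights)

#' Load an AFM height map
#'
#' Reads a 2D height grid from a single-channel TIFF or a plain-text array
#' dump (CSV/TSV/whitespace table, one image row per line).  Values are taken
#' as nanometres and left untouched; the pixel size must be supplied by the
#' caller since neither format carries a reliable calibration.
#'
#' @param path file path (`.tif`/`.tiff`, `.csv`, `.tsv`, `.txt`).
#' @param pixel_size_nm nm per pixel.
#' @param source_id provenance tag; defaults to the file name.
#' @return an `afm_heightmap`.
#' @export
load_heightmap <- function(path, pixel_size_nm, source_id = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(m)) != 2L) {
      stop("expected a single-channel 2D image, got dimensions ",
           paste(dim(m), collapse = " x "))
    }
  } else {
    sep <- if (ext == "csv") "," else if (ext == "tsv") "\t" else ""
    m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    if (!is.numeric(m)) stop("non-numeric values in ", path)
  }
  if (!all(is.finite(m))) stop("non-finite values in ", path)
  heightmap(m, pixel_size_nm, source_id)
}

#' Write a height map
#'
#' Plain-text grids (`.csv`, `.tsv`, `.txt`) are written at full double
#' precision and round-trip exactly through [load_heightmap()].  TIFF output
#' is supported only after linear rescaling to `[0, 1]` (the TIFF writer does
#' not preserve out-of-range floats), so it is for visualisation, not
#' storage.
#'
#' @param hm an `afm_heightmap`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_heightmap <- function(hm, path) {
  stopifnot(inherits(hm, "afm_heightmap"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    h <- hm$heights
    rg <- range(h)
    if (diff(rg) > 0) h <- (h - rg[1]) / diff(rg)
    tiff::writeTIFF(h, path, bits.per.sample = 16L)
  } else {
    sep <- if (ext == "csv") "," else if (ext == "tsv") "\t" else " "
    txt <- apply(hm$heights, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = sep))
    writeLines(txt, path)
  }
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a height map
#'
#' @param object an `afm_heightmap`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.afm_heightmap <- function(object, ...) {
  df <- heightmap_df(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                   fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("#2c1a4d", "#b3589a",
                                              "#f8a07e", "#fde8c8"),
                                  name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

heightmap_df <- function(hm) {
  h <- hm$heights
  tibble::tibble(
    row = rep(seq_len(nrow(h)) - 1L, times = ncol(h)),
    col = rep(seq_len(ncol(h)) - 1L, each = nrow(h)),
    height_nm = as.vector(h)
  ) |>
    dplyr::mutate(x_nm = .data$col * hm$pixel_size_nm,
                  y_nm = .data$row * hm$pixel_size_nm)
}

#' @importFrom rlang .data
NULL
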