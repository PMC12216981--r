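#' Flattening configuration
#'
#' @param gaussian_px sigma (in pixels) of the final Gaussian denoising
#'   filter; 1.1 px by default, 0 disables smoothing.
#' @param background_sigma pixels below this many robust standard deviations
#'   above the median are treated as background when re-fitting tilt terms.
#' @param scar_threshold_nm a pixel is a scar candidate when it differs from
#'   both vertical neighbours by more than this, with the same sign.
#' @param scar_min_run minimum horizontal run length (px) of scar candidates.
#' @return a list of class `flatten_config`.
#' @export
flatten_config <- function(gaussian_px = 1.1, background_sigma = 1,
                           scar_threshold_nm = 0.75, scar_min_run = 3L) {
  structure(list(gaussian_px = gaussian_px,
                 background_sigma = background_sigma,
                 scar_threshold_nm = scar_threshold_nm,
                 scar_min_run = as.integer(scar_min_run)),
            class = "flatten_config")
}

#' Flatten an AFM height map
#'
#' Removes the background structure typical of raw AFM topographs: best-fit
#' plane, quadratic bow, per-row (scan-line) median offsets, and single-row
#' scar streaks; the background is then re-levelled to zero and a light
#' Gaussian filter suppresses high-gain noise.  Tilt terms are estimated on
#' background pixels only (heights below `background_sigma` robust standard
#' deviations above the median, with the spread estimated by the median
#' absolute deviation so bright molecules do not inflate it).
#'
#' @param hm an `afm_heightmap`.
#' @param cfg a [flatten_config()].
#' @return the flattened `afm_heightmap`; after flattening the background
#'   mode is within 0.1 nm of zero.
#' @export
flatten <- function(hm, cfg = flatten_config()) {
  stopifnot(inherits(hm, "afm_heightmap"))
  h <- hm$heights
  if (nrow(h) < 8L || ncol(h) < 8L) {
    stop("image too small to flatten (need at least 8 x 8 pixels)")
  }
  xy <- pixel_grid(h)
  # first-pass plane on all pixels so the background mask is meaningful
  h <- h - fit_surface(h, xy, quadratic = FALSE)
  bg <- background_mask(h, cfg$background_sigma)
  h <- h - fit_surface(h, xy, quadratic = FALSE, mask = bg)
  bg <- background_mask(h, cfg$background_sigma)
  h <- h - fit_surface(h, xy, quadratic = TRUE, mask = bg)
  bg <- background_mask(h, cfg$background_sigma)
  h <- h - row_median_offsets(h, bg)
  h <- remove_scars(h, cfg$scar_threshold_nm, cfg$scar_min_run)
  bg <- background_mask(h, cfg$background_sigma)
  h <- h - mean(h[bg])
  if (cfg$gaussian_px > 0) h <- gaussian_blur(h, cfg$gaussian_px)
  heightmap(h, hm$pixel_size_nm, hm$source_id)
}

pixel_grid <- function(h) {
  list(x = matrix(rep(seq_len(ncol(h)), each = nrow(h)), nrow(h)) / ncol(h),
       y = matrix(rep(seq_len(nrow(h)), times = ncol(h)), nrow(h)) / nrow(h))
}

background_mask <- function(h, k) {
  s <- stats::mad(h)
  if (s == 0) s <- stats::sd(h)
  if (!is.finite(s) || s == 0) return(matrix(TRUE, nrow(h), ncol(h)))
  h <= stats::median(h) + k * s
}

fit_surface <- function(h, xy, quadratic, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(h), ncol(h))
  x <- xy$x[mask]; y <- xy$y[mask]; z <- h[mask]
  X <- if (quadratic) cbind(1, x, y, x^2, y^2, x * y) else cbind(1, x, y)
  beta <- stats::lm.fit(X, z)$coefficients
  beta[!is.finite(beta)] <- 0
  xf <- as.vector(xy$x); yf <- as.vector(xy$y)
  Xf <- if (quadratic) cbind(1, xf, yf, xf^2, yf^2, xf * yf) else cbind(1, xf, yf)
  matrix(Xf %*% beta, nrow(h))
}

row_median_offsets <- function(h, bg) {
  off <- vapply(seq_len(nrow(h)), function(i) {
    v <- h[i, bg[i, ]]
    if (length(v) < 4L) stats::median(h[i, ]) else stats::median(v)
  }, 0)
  matrix(off, nrow(h), ncol(h))
}

remove_scars <- function(h, thr, min_run) {
  n <- nrow(h)
  if (n < 3L) return(h)
  up <- h[2:(n - 1), ] - h[1:(n - 2), ]
  dn <- h[2:(n - 1), ] - h[3:n, ]
  cand <- abs(up) > thr & abs(dn) > thr & sign(up) == sign(dn)
  for (i in seq_len(n - 2L)) {
    r <- rle(cand[i, ])
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (r$values[j] && r$lengths[j] >= min_run) {
        cols <- pos[j]:(pos[j + 1L] - 1L)
        h[i + 1L, cols] <- (h[i, cols] + h[i + 2L, cols]) / 2
      }
    }
  }
  h
}

# separable Gaussian convolution with edge replication
gaussian_blur <- function(h, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) {
    rbind(m[rep(1L, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE])
  }
  conv_cols <- function(m) {
    p <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * p[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(h))))
}
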