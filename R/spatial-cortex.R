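# Where structures live inside droplets: radial probability profiles P(r/R),
# temporal cross-correlation of binarized projections, and the spatial
# correlation C(s) of the cortex signal with its correlation length xi_c.

#' Radial probability profile of a binarized slice
#'
#' The circular average of a binarized image: for each radial bin in r/R, the
#' probability is the fraction of TRUE pixels among the pixels whose
#' normalized distance from the droplet centre falls in that bin.
#'
#' @param mask binarized raster (structures), restricted to the droplet.
#' @param center droplet centre `(x, y)` in um.
#' @param R droplet radius in um.
#' @param pixel_size um per pixel.
#' @param n_bins number of uniform bins in r/R over `[0, 1]`.
#' @return data.frame with `r_over_R` (bin centres), `probability`,
#'   `n_pixels` and a `sparse` flag for bins with < 10 pixels.
#' @export
radial_probability <- function(mask, center, R, pixel_size, n_bins = 20) {
  mask <- mask != 0
  if (R <= 0) stop("droplet radius must be positive", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  X <- matrix(rep((seq_len(nc) - 1) * pixel_size, each = nr), nr)
  Y <- matrix(rep((seq_len(nr) - 1) * pixel_size, nc), nr)
  rr <- sqrt((X - center[1])^2 + (Y - center[2])^2) / R
  inside <- rr <= 1
  bin <- pmin(floor(rr[inside] * n_bins), n_bins - 1) + 1
  vals <- mask[inside]
  npx <- tabulate(bin, n_bins)
  prob <- vapply(seq_len(n_bins), function(b)
    if (npx[b] > 0) mean(vals[bin == b]) else NA_real_, numeric(1))
  data.frame(r_over_R = (seq_len(n_bins) - 0.5) / n_bins,
             probability = prob, n_pixels = npx, sparse = npx < 10)
}

#' Temporal cross-correlation of binarized projections
#'
#' Pearson correlation between the first frame and every frame, over an
#' optional ROI; measures how much the cortex pattern has reorganized.
#'
#' @param masks list of co-registered binarized rasters (>= 2).
#' @param roi optional logical raster restricting the comparison.
#' @return data.frame with `frame` and `correlation` (`NA` with a warning for
#'   constant frames).
#' @export
temporal_cross_correlation <- function(masks, roi = NULL) {
  stopifnot(is.list(masks), length(masks) >= 2)
  ref <- masks[[1]] != 0
  roi <- roi %||% matrix(TRUE, nrow(ref), ncol(ref))
  v0 <- as.numeric(ref[roi])
  corrs <- vapply(seq_along(masks), function(i) {
    vi <- as.numeric((masks[[i]] != 0)[roi])
    if (sd(v0) == 0 || sd(vi) == 0) {
      warning("constant mask at frame ", i, ": correlation undefined")
      return(NA_real_)
    }
    cor(v0, vi)
  }, numeric(1))
  data.frame(frame = seq_along(masks), correlation = corrs)
}

#' Circular autocorrelation of a cortex trace and its correlation length
#'
#' `C(lag)` is the normalized circular autocorrelation of the mean-subtracted
#' signal (`C(0) = 1`); the correlation length `xi_c` is the smallest
#' arclength lag at which C first falls below 1/e, by linear interpolation
#' between samples.
#'
#' @param signal periodic signal sampled along the contour (>= 50 samples).
#' @param spacing arclength spacing between samples (um).
#' @return list of class `contour_correlation`: `lag_um`, `C`, `xi_c_um`.
#' @export
contour_correlation <- function(signal, spacing) {
  n <- length(signal)
  if (n < 50) stop("contour trace needs >= 50 samples", call. = FALSE)
  x <- signal - mean(signal)
  if (var(x) == 0)
    stop("zero-variance cortex signal: correlation undefined", call. = FALSE)
  # circular autocorrelation via FFT
  f <- fft(x)
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / n
  C <- ac / ac[1]
  lags <- (seq_len(n) - 1) * spacing
  half <- seq_len(floor(n / 2) + 1)      # C is even in lag; report half
  Ch <- C[half]; lh <- lags[half]
  target <- exp(-1)
  below <- which(Ch < target)
  xi <- if (length(below) == 0) {
    NA_real_
  } else {
    i <- below[1]
    if (i == 1) 0
    else approx(Ch[c(i - 1, i)], lh[c(i - 1, i)], target)$y
  }
  structure(list(lag_um = lh, C = Ch, xi_c_um = xi),
            class = "contour_correlation")
}

#' Cortex signal along a shell band
#'
#' For each contour vertex, the mean image intensity sampled along the ray
#' from the droplet centroid through that vertex over the radial band
#' `[R - band_width, R]` (R = distance centroid-to-vertex).
#'
#' @param image raster (intensity or binarized).
#' @param contour a [extract_contour()] result.
#' @param band_width band width in um; must be smaller than the droplet
#'   radius.
#' @param pixel_size um per pixel.
#' @param n_radial radial samples per vertex.
#' @return list of class `cortex_trace`: `s_um` (arclength), `signal`,
#'   `spacing_um`.
#' @export
shell_band_signal <- function(image, contour, band_width, pixel_size,
                              n_radial = 10) {
  stop_if_not_raster(image)
  stopifnot(inherits(contour, "droplet_contour"))
  ctr <- contour$centroid
  rad <- sqrt((contour$x - ctr[1])^2 + (contour$y - ctr[2])^2)
  if (band_width >= min(rad))
    stop("band wider than the droplet radius", call. = FALSE)
  sig <- vapply(seq_along(contour$x), function(i) {
    ux <- (contour$x[i] - ctr[1]) / rad[i]
    uy <- (contour$y[i] - ctr[2]) / rad[i]
    rs <- seq(rad[i] - band_width, rad[i], length.out = n_radial)
    mean(bilinear(image, (ctr[1] + ux * rs) / pixel_size,
                  (ctr[2] + uy * rs) / pixel_size))
  }, numeric(1))
  structure(list(s_um = contour$s, signal = sig,
                 spacing_um = contour$perimeter_um / length(sig)),
            class = "cortex_trace")
}
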