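# Two-channel acridine-orange unmixing and cortex release kinetics.
#
# Acridine orange emits green on dsDNA and red on ssDNA, but also stains the
# peptide itself in both channels. With the peptide bleed-through ratio
# beta = I_green,FF / I_red,FF measured on a peptide-only sample, the map
# I_green - beta * I_red equals I_dsDNA - beta * I_ssDNA, a per-pixel
# hybridization contrast that is independent of the peptide signal.

#' Estimate the peptide bleed-through ratio beta
#'
#' Pixelwise median of green/red over the foreground of a peptide-only
#' sample (median rather than mean: robust to segmentation bleed and
#' DNA-positive contamination).
#'
#' @param green,red background-subtracted channel rasters.
#' @param foreground logical mask of peptide-only pixels (>= 100).
#' @return object of class `unmix_model`: `beta`, `beta_mad` (spread),
#'   `n_pixels`.
#' @export
estimate_beta <- function(green, red, foreground) {
  stop_if_not_raster(green); stop_if_not_raster(red)
  stopifnot(all(dim(green) == dim(red)), all(dim(green) == dim(foreground)))
  foreground <- foreground != 0
  if (sum(foreground) < 100)
    stop("need >= 100 foreground pixels to estimate beta", call. = FALSE)
  r <- red[foreground]; g <- green[foreground]
  bad <- mean(r <= 0)
  if (bad > 0.05)
    stop(sprintf("red channel non-positive on %.1f%% of foreground", 100 * bad),
         call. = FALSE)
  ok <- r > 0
  ratio <- g[ok] / r[ok]
  structure(list(beta = median(ratio),
                 beta_mad = stats::mad(ratio),
                 n_pixels = sum(ok)),
            class = "unmix_model")
}

#' Unmix the DNA hybridization contrast
#'
#' `map = green - beta * red`; positive values indicate local dsDNA excess,
#' negative values ssDNA excess. Values are signed and never clamped.
#'
#' @param green,red aligned, background-subtracted channel rasters.
#' @param model an [estimate_beta()] result, or a bare beta value.
#' @return signed raster of the same shape.
#' @export
unmix <- function(green, red, model) {
  stop_if_not_raster(green); stop_if_not_raster(red)
  if (!all(dim(green) == dim(red)))
    stop("channel shapes differ", call. = FALSE)
  beta <- if (inherits(model, "unmix_model")) model$beta else model
  stopifnot(is.numeric(beta), beta >= 0)
  green - beta * red
}

#' Bleach-corrected cortex intensity over time
#'
#' Mean intensity over the cortex band of each acquisition, divided by the
#' per-acquisition photobleach factor; optionally normalized by a reference
#' intensity (e.g. the mean cortex intensity of control droplets).
#'
#' @param images list of rasters over time (one droplet, registered).
#' @param contour a [extract_contour()] result for the droplet.
#' @param times acquisition times (min).
#' @param pixel_size um per pixel.
#' @param bleach_factors per-acquisition factors from
#'   [photobleach_factors()]; default all 1.
#' @param band_width cortex band width in um (default 10% of the droplet
#'   radius).
#' @param reference optional normalization intensity.
#' @return data.frame of class `release_curve`: `t_min`, `intensity`.
#' @export
cortex_intensity_series <- function(images, contour, times, pixel_size,
                                    bleach_factors = NULL, band_width = NULL,
                                    reference = NULL) {
  stopifnot(is.list(images), length(images) == length(times),
            inherits(contour, "droplet_contour"))
  bleach_factors <- bleach_factors %||% rep(1, length(images))
  stopifnot(length(bleach_factors) == length(images))
  ctr <- contour$centroid
  rad <- mean(sqrt((contour$x - ctr[1])^2 + (contour$y - ctr[2])^2))
  band_width <- band_width %||% (0.1 * rad)
  vals <- vapply(seq_along(images), function(i) {
    tr <- shell_band_signal(images[[i]], contour, band_width, pixel_size)
    mean(tr$signal) / bleach_factors[i]
  }, numeric(1))
  if (!is.null(reference)) vals <- vals / reference
  out <- data.frame(t_min = times, intensity = vals)
  class(out) <- c("release_curve", "data.frame")
  out
}

#' Fit single-exponential release kinetics
#'
#' Nonlinear least squares of `I(t) = Iinf + (I0 - Iinf) exp(-k t)` with a
#' residual-resampling bootstrap confidence interval for the decay constant.
#'
#' @param curve data.frame with `t_min` and `intensity` (>= 5 points), e.g.
#'   a [cortex_intensity_series()] result.
#' @param n_boot bootstrap replicates (default 200).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return object of class `release_fit`: `k` (1/min), `k_ci`, `I0`, `Iinf`,
#'   `flat` (TRUE when the interval includes 0), `fit`.
#' @export
fit_release <- function(curve, n_boot = 200, seed = 1, conf = 0.95) {
  stopifnot(all(c("t_min", "intensity") %in% names(curve)),
            nrow(curve) >= 5)
  t <- curve$t_min; I <- curve$intensity
  span <- diff(range(t))
  fit1 <- function(tt, II) {
    i0 <- II[1]; iinf <- min(II)
    k0 <- max(1 / span, 1e-6)
    f <- tryCatch(
      minpack.lm::nlsLM(II ~ iinf_ + (i0_ - iinf_) * exp(-k_ * tt),
                        start = list(i0_ = i0, iinf_ = iinf, k_ = k0),
                        lower = c(-Inf, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f)) return(NULL)
    cf <- coef(f)
    list(k = unname(cf["k_"]), I0 = unname(cf["i0_"]),
         Iinf = unname(cf["iinf_"]), fit = f)
  }
  main <- fit1(t, I)
  if (is.null(main)) {
    # near-constant curves have no identifiable rate: report k = 0
    if (sd(I) < 1e-9 * max(abs(I), 1))
      return(structure(list(k = 0, k_ci = c(0, 0), I0 = mean(I),
                            Iinf = mean(I), flat = TRUE, fit = NULL),
                       class = "release_fit"))
    stop("release fit failed to converge", call. = FALSE)
  }
  pred <- predict(main$fit)
  res <- I - pred
  ks <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    Ib <- pred + sample(res, length(res), replace = TRUE)
    fb <- fit1(t, Ib)
    if (is.null(fb)) NA_real_ else fb$k
  }, numeric(1)))
  ks <- ks[!is.na(ks)]
  alpha <- (1 - conf) / 2
  ci <- if (length(ks) >= 10) unname(quantile(ks, c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  flat <- !is.na(ci[1]) && ci[1] <= 1e-12
  structure(list(k = main$k, k_ci = ci, I0 = main$I0, Iinf = main$Iinf,
                 flat = flat, fit = main$fit),
            class = "release_fit")
}

#' @export
print.release_fit <- function(x, ...) {
  cat(sprintf("<release_fit> k = %.4g /min [%.4g, %.4g], I0 = %.4g, Iinf = %.4g%s\n",
              x$k, x$k_ci[1], x$k_ci[2], x$I0, x$Iinf,
              if (x$flat) " (consistent with no release)" else ""))
  invisible(x)
}
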