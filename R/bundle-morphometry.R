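# Bundle / tactoid morphometry: segmentation of condensed filament bundles,
# length/width/aspect-ratio measurement, thin/large classification, intensity
# line scans, the aspect-ratio vs crosslinker-fraction power law, and a
# structure-tensor alignment fraction.

#' Segment bundles from a binary mask
#'
#' Each 8-connected component of at least `min_area` is measured: length is
#' the mean of the end-capped geodesic skeleton length (longest skeleton path
#' plus the distance-transform radii at its two ends) and the maximum Feret
#' diameter -- the two bracket the tip-to-tip length from below and above;
#' width is twice the mean distance-transform value along the skeleton path;
#' orientation comes from the second moments of the pixel coordinates.
#'
#' When the intensity `image` is supplied, a per-object dilation correction
#' is applied: a detection mask thresholded near the noise floor (needed to
#' keep the dim tapered tips of tactoids) is dilated by the point-spread
#' blur, isotropically; the half-maximum contour, by contrast, sits on the
#' true edge of a blurred step. The length is then the Feret diameter of the
#' detection mask minus the width excess over the half-maximum width, and
#' the reported width is the half-maximum width.
#'
#' @param mask logical/0-1 matrix (binarized image).
#' @param pixel_size um per pixel.
#' @param min_area minimum component area in um^2.
#' @param image optional intensity raster the mask was derived from, for the
#'   dilation correction.
#' @param background background level of `image`; estimated from the
#'   intensity histogram when omitted.
#' @return data.frame of bundle records: `label`, `length_um`, `width_um`,
#'   `aspect_ratio`, `orientation_rad`, `centroid_x_um`, `centroid_y_um`,
#'   `area_um2`.
#' @export
segment_bundles <- function(mask, pixel_size, min_area = 0.5, image = NULL,
                            background = NULL) {
  if (!is.null(image) && is.null(background))
    background <- estimate_background(image)
  mask <- mask != 0
  stopifnot(pixel_size > 0)
  if (!any(mask)) {
    warning("empty mask: no bundles")
    return(data.frame(label = integer(), length_um = numeric(),
                      width_um = numeric(), aspect_ratio = numeric(),
                      orientation_rad = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), area_um2 = numeric()))
  }
  lab <- as_matrix(EBImage::bwlabel(ebi(mask * 1)))
  recs <- lapply(seq_len(max(lab)), function(l) {
    full <- lab == l
    area <- sum(full) * pixel_size^2
    if (area < min_area) return(NULL)
    # work on the component's bounding box (1 px margin)
    w <- which(full, arr.ind = TRUE)
    r0 <- max(min(w[, 1]) - 1, 1); r1 <- min(max(w[, 1]) + 1, nrow(full))
    c0 <- max(min(w[, 2]) - 1, 1); c1 <- min(max(w[, 2]) + 1, ncol(full))
    comp <- full[r0:r1, c0:c1, drop = FALSE]
    dt <- as_matrix(EBImage::distmap(ebi(comp * 1)))
    sp <- skeleton_path_info(comp)
    pix <- sp$pixels
    dvals <- dt[cbind(pix[, 1], pix[, 2])]
    n <- nrow(pix)
    skel_px <- sp$length_px + dvals[1] + dvals[n]
    feret_px <- feret_max_px(comp)
    width_px <- 2 * mean(dvals)
    if (!is.null(image)) {
      sub <- image[r0:r1, c0:c1, drop = FALSE]
      peak <- quantile(sub[comp], 0.98)
      half <- comp & sub >= background + 0.5 * (peak - background)
      if (sum(half) >= 4) {
        dt_h <- as_matrix(EBImage::distmap(ebi(half * 1)))
        dv_h <- dt_h[cbind(pix[, 1], pix[, 2])]
        width_half_px <- 2 * mean(dv_h[dv_h > 0])
        # isotropic dilation: the axial excess equals the lateral excess
        length_px <- feret_px - max(width_px - width_half_px, 0)
        width_px <- width_half_px
      } else length_px <- (min(skel_px, feret_px) + feret_px) / 2
    } else {
      # without intensity data the end-capped skeleton (under-reads tapered
      # tips) and the Feret diameter (over-reads dilated boundaries) bracket
      # the tip-to-tip length; their mean cancels the bias to first order
      length_px <- (min(skel_px, feret_px) + feret_px) / 2
    }
    len <- length_px * pixel_size
    wid <- width_px * pixel_size
    if (len < wid) { tmp <- len; len <- wid; wid <- tmp }  # disks etc.
    idx <- which(full, arr.ind = TRUE)
    cx <- mean(idx[, 2] - 1) * pixel_size
    cy <- mean(idx[, 1] - 1) * pixel_size
    # orientation from second central moments (x right, y down)
    mu20 <- var(idx[, 2]); mu02 <- var(idx[, 1])
    mu11 <- if (nrow(idx) > 1) cov(idx[, 2], idx[, 1]) else 0
    ori <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    data.frame(label = l, length_um = len, width_um = wid,
               aspect_ratio = len / wid, orientation_rad = ori,
               centroid_x_um = cx, centroid_y_um = cy, area_um2 = area)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    warning("no components above min_area")
    out <- data.frame(label = integer(), length_um = numeric(),
                      width_um = numeric(), aspect_ratio = numeric(),
                      orientation_rad = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), area_um2 = numeric())
  }
  out
}

# Max pairwise distance between pixel-corner hull vertices (Feret diameter).
feret_max_px <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  xs <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5)
  ys <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5)
  h <- chull(xs, ys)
  max(dist(cbind(xs[h], ys[h])))
}

#' Classify bundles as thin or large by width
#'
#' Thin iff `width < width_threshold` (strict; a width exactly at the
#' threshold is "large").
#'
#' @param records data.frame from [segment_bundles()].
#' @param width_threshold um; default 1.
#' @return `records` with a `size_class` column; the threshold used is
#'   attached as attribute `"width_threshold"`.
#' @export
classify_bundles <- function(records, width_threshold = 1.0) {
  stopifnot(is.data.frame(records), "width_um" %in% names(records))
  records$size_class <- ifelse(records$width_um < width_threshold,
                               "thin", "large")
  attr(records, "width_threshold") <- width_threshold
  records
}

#' Intensity line scan with peak detection
#'
#' Samples the image by bilinear interpolation along the segment `p0 -> p1`,
#' then finds local maxima above `mean + 1 SD` separated by at least two
#' sampling steps; peak widths are full widths at half prominence.
#'
#' @param image raster.
#' @param p0,p1 endpoints `(x, y)` in um.
#' @param pixel_size um per pixel.
#' @param sampling sample spacing in um (default half a pixel).
#' @return list with `positions` (um), `intensities`, `peaks` (data.frame of
#'   `position_um`, `height`, `fwhm_um`).
#' @export
line_scan <- function(image, p0, p1, pixel_size, sampling = pixel_size / 2) {
  stop_if_not_raster(image)
  if (all(p0 == p1)) stop("line-scan endpoints coincide", call. = FALSE)
  len <- sqrt(sum((p1 - p0)^2))
  pos <- seq(0, len, by = sampling)
  fx <- p0[1] + (p1[1] - p0[1]) * pos / len
  fy <- p0[2] + (p1[2] - p0[2]) * pos / len
  vals <- bilinear(image, fx / pixel_size, fy / pixel_size)
  thresh <- mean(vals) + sd(vals)
  pk <- pracma::findpeaks(vals, minpeakheight = thresh,
                          minpeakdistance = 2, zero = "0")
  peaks <- data.frame(position_um = numeric(), height = numeric(),
                      fwhm_um = numeric())
  if (!is.null(pk)) {
    base <- min(vals)
    for (r in seq_len(nrow(pk))) {
      ip <- pk[r, 2]
      half <- base + (pk[r, 1] - base) / 2
      li <- ip; while (li > 1 && vals[li] > half) li <- li - 1
      ri <- ip; while (ri < length(vals) && vals[ri] > half) ri <- ri + 1
      xl <- if (vals[li] <= half && li < ip)
        approx(vals[c(li, li + 1)], pos[c(li, li + 1)], half)$y else pos[li]
      xr <- if (vals[ri] <= half && ri > ip)
        approx(vals[c(ri - 1, ri)], pos[c(ri - 1, ri)], half)$y else pos[ri]
      peaks <- rbind(peaks, data.frame(position_um = pos[ip],
                                       height = pk[r, 1],
                                       fwhm_um = xr - xl))
    }
  }
  list(positions = pos, intensities = vals, peaks = peaks)
}

#' Power-law fit of aspect ratio versus crosslinker fraction
#'
#' Ordinary least squares of `log(y)` on `log(x)`; the slope is the scaling
#' exponent.
#'
#' @param x crosslinker fractions (mol%), all positive, >= 3 distinct values.
#' @param y aspect ratios, all positive.
#' @return object of class `power_law_fit`: `exponent`, `exponent_se`,
#'   `prefactor`, `r_squared`, and the underlying `lm` fit.
#' @export
fit_power_law <- function(x, y) {
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit needs strictly positive x and y", call. = FALSE)
  if (length(unique(x)) < 3)
    stop("power-law fit needs >= 3 distinct x values", call. = FALSE)
  fit <- lm(log(y) ~ log(x))
  sm <- summary(fit)
  structure(list(exponent = unname(coef(fit)[2]),
                 exponent_se = sm$coefficients[2, 2],
                 prefactor = exp(unname(coef(fit)[1])),
                 r_squared = sm$r.squared,
                 fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent = %.3f +- %.3f, prefactor = %.3g, R^2 = %.3f\n",
              x$exponent, x$exponent_se, x$prefactor, x$r_squared))
  invisible(x)
}

#' Alignment fraction by structure-tensor coherence
#'
#' Per-pixel coherence `(l1 - l2) / (l1 + l2)` of the smoothed structure
#' tensor (1 for a perfectly oriented pattern, 0 for isotropic texture); the
#' alignment fraction is the intensity-weighted mean coherence over the
#' foreground (Otsu).
#'
#' @param image raster, non-constant.
#' @param pixel_size um per pixel.
#' @param tensor_sigma tensor smoothing scale in um.
#' @return alignment fraction in `[0, 1]`.
#' @export
orientation_coherence <- function(image, pixel_size, tensor_sigma = 1) {
  stop_if_not_raster(image)
  if (diff(range(image)) == 0)
    stop("orientation coherence undefined for a constant image", call. = FALSE)
  # central-difference gradients (x = columns, y = rows)
  gx <- (shift_mat(image, 0, -1) - shift_mat(image, 0, 1)) / 2
  gy <- (shift_mat(image, -1, 0) - shift_mat(image, 1, 0)) / 2
  sig_px <- max(tensor_sigma / pixel_size, 0.5)
  Jxx <- as_matrix(EBImage::gblur(ebi(gx * gx), sigma = sig_px))
  Jyy <- as_matrix(EBImage::gblur(ebi(gy * gy), sigma = sig_px))
  Jxy <- as_matrix(EBImage::gblur(ebi(gx * gy), sigma = sig_px))
  tr <- Jxx + Jyy
  coh <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / pmax(tr, .Machine$double.eps)
  coh[tr <= 0] <- 0
  fg <- image >= otsu_threshold(image)
  # trim one-pixel border where the gradients are one-sided
  fg[c(1, nrow(fg)), ] <- FALSE; fg[, c(1, ncol(fg))] <- FALSE
  w <- image * fg
  sum(coh * w) / sum(w)
}
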