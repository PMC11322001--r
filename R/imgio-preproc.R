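# Calibrated image stacks and the standard confocal preprocessing chain:
# flat-field (illumination) correction, background subtraction, photobleach
# correction, binarization, z projection.

#' Construct a calibrated image stack
#'
#' @param pixels numeric array with axes `(t, z, c, y, x)`; lower-dimensional
#'   input (a matrix, or a 3-D `(z, y, x)` array) is promoted with singleton
#'   axes.
#' @param pixel_size um per pixel.
#' @param frame_times optional acquisition times (s), one per t.
#' @param channel_names optional channel labels.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size, frame_times = NULL,
                        channel_names = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(1, 1, 1, dim(pixels))
  if (length(dim(pixels)) == 3) dim(pixels) <- c(1, 1, dim(pixels))
  if (length(dim(pixels)) == 4) dim(pixels) <- c(1, dim(pixels))
  stopifnot(length(dim(pixels)) == 5, pixel_size > 0, all(is.finite(pixels)))
  d <- dim(pixels)
  if (!is.null(frame_times)) stopifnot(length(frame_times) == d[1])
  if (!is.null(channel_names)) stopifnot(length(channel_names) == d[3])
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_times = frame_times,
                 channel_names = channel_names %||% paste0("ch", seq_len(d[3]))),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> t=%d z=%d c=%d %dx%d px, %.3g um/px\n",
              d[1], d[2], d[3], d[4], d[5], x$pixel_size))
  invisible(x)
}

#' Extract one (t, z, c) plane as a matrix
#' @param stack an [image_stack()].
#' @param t,z,c plane indices.
#' @return numeric matrix (rows = y, cols = x).
#' @export
get_plane <- function(stack, t = 1, z = 1, c = 1) {
  stopifnot(inherits(stack, "image_stack"))
  m <- stack$pixels[t, z, c, , ]
  dim(m) <- dim(stack$pixels)[4:5]
  m
}

#' Maximum z projection
#'
#' Per-pixel maximum over the z axis for one time point and channel.
#' @inheritParams get_plane
#' @return numeric matrix.
#' @export
max_z_projection <- function(stack, t = 1, c = 1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  planes <- stack$pixels[t, , c, , ]
  dim(planes) <- d[c(2, 4, 5)]
  apply(planes, c(2, 3), max)
}

#' Write an image stack as a multi-page TIFF with a sidecar JSON
#'
#' Pages are ordered t-major, then z, then c; calibration (pixel size, axis
#' lengths, frame times, channel names) goes into `<path>.json`.
#' @param stack an [image_stack()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  mx <- max(stack$pixels, 1)
  pages <- list()
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3]))
    pages[[length(pages) + 1]] <- get_plane(stack, t, z, ch) / mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(axes = "tzcyx", dim = d, pixel_size_um = stack$pixel_size,
               intensity_scale = mx, frame_times_s = stack$frame_times,
               channel_names = stack$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#' @param path `.tif` path (expects `<path>.json` sidecar).
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    d <- as.integer(meta$dim)
    scale <- meta$intensity_scale %||% 1
    px <- meta$pixel_size_um
    ft <- meta$frame_times_s
    cn <- meta$channel_names
  } else {
    d <- c(length(pages), 1L, 1L, dim(pages[[1]]))
    scale <- 1; px <- 1; ft <- NULL; cn <- NULL
  }
  arr <- array(0, d)
  i <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    i <- i + 1L
    arr[t, z, ch, , ] <- pages[[i]] * scale
  }
  image_stack(arr, px, frame_times = ft, channel_names = cn)
}

# ---- flat-field -------------------------------------------------------------

#' Build a flat-field map from a homogeneous dye image
#'
#' `factors = (dye - background) / mean(dye - background)`; the map has mean
#' exactly 1 and divides out illumination inhomogeneity.
#'
#' @param dye_image raster of a homogeneously fluorescent sample.
#' @param background scalar or raster background level.
#' @param tol maximum tolerated fraction of non-positive corrected pixels.
#' @return object of class `flatfield_map` (matrix `factors` with mean 1).
#' @export
build_flatfield <- function(dye_image, background = 0, tol = 0.01) {
  stop_if_not_raster(dye_image)
  corr <- dye_image - background
  bad <- mean(corr <= 0)
  if (bad > tol)
    stop(sprintf("dye image not above background: %.1f%% of pixels non-positive",
                 100 * bad), call. = FALSE)
  corr[corr <= 0] <- min(corr[corr > 0])
  factors <- corr / mean(corr)
  structure(list(factors = factors), class = "flatfield_map")
}

#' Apply a flat-field map
#'
#' `corrected = (image - background) / factors`, clamped at 0.
#' @param image raster to correct.
#' @param map a [build_flatfield()] result.
#' @param background scalar background of the sample image.
#' @return corrected raster.
#' @export
apply_flatfield <- function(image, map, background = 0) {
  stop_if_not_raster(image)
  stopifnot(inherits(map, "flatfield_map"))
  if (!all(dim(image) == dim(map$factors)))
    stop("image and flat-field map shapes differ", call. = FALSE)
  pmax((image - background) / map$factors, 0)
}

# ---- photobleaching ---------------------------------------------------------

#' Per-acquisition photobleach factors from a non-releasing control
#'
#' The foreground ROI is fixed from the first acquisition (Otsu), so that
#' bleaching itself cannot shrink the ROI; `factor_i` is the mean foreground
#' intensity of acquisition i relative to acquisition 1. Factors above
#' `1 + tol` trigger a warning and are clamped at 1.
#'
#' @param control_series list of >= 3 rasters of a non-releasing sample.
#' @param tol tolerance on increasing intensity before clamping.
#' @return numeric vector of factors, first element 1.
#' @export
photobleach_factors <- function(control_series, tol = 0.02) {
  stopifnot(is.list(control_series), length(control_series) >= 3)
  ref <- control_series[[1]]
  fg <- if (diff(range(ref)) > 0) ref >= otsu_threshold(ref)
        else matrix(TRUE, nrow(ref), ncol(ref))
  means <- vapply(control_series, function(im) mean(im[fg]), numeric(1))
  factors <- means / means[1]
  if (any(factors > 1 + tol)) {
    warning("photobleach factor > 1 beyond tolerance; clamped at 1")
    factors <- pmin(factors, 1)
  }
  factors
}

#' Divide a series of acquisitions by its photobleach factors
#' @param series list of rasters.
#' @param factors from [photobleach_factors()].
#' @return list of corrected rasters.
#' @export
correct_photobleach <- function(series, factors) {
  stopifnot(length(series) == length(factors))
  Map(function(im, f) im / f, series, factors)
}

# ---- binarization -----------------------------------------------------------

#' Binarize a raster
#'
#' @param image raster.
#' @param method `"otsu"` (default, parameter-free) or `"fixed"`.
#' @param threshold required for `method = "fixed"`.
#' @return logical mask (`TRUE` where `intensity >= threshold`) with the
#'   threshold used attached as attribute `"threshold"`.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stop_if_not_raster(image)
  th <- switch(method,
    otsu = otsu_threshold(image),
    fixed = {
      if (is.null(threshold)) stop("fixed method needs a threshold", call. = FALSE)
      threshold
    })
  structure(image >= th, threshold = th)
}
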