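# Droplet shape descriptors: contour extraction, inscribed/circumscribed
# circle sphericity, solidity (area / convex hull), local curvature profiles
# and the sphericity-versus-size threshold fit.

#' Extract the droplet contour from a binary mask
#'
#' Marching-squares boundary at the 0.5 level (via [grDevices::contourLines()])
#' of the hole-filled largest component, ordered counter-clockwise and lightly
#' smoothed with a circular moving average.
#'
#' @param mask logical/0-1 matrix with one filled component (>= 100 px).
#' @param pixel_size um per pixel.
#' @param smooth_window moving-average window (vertices, odd); logged as an
#'   attribute.
#' @return object of class `droplet_contour`: `x`, `y` (um), `s` (arclength,
#'   um), `perimeter_um`, `centroid` and the mask-derived `center`/`area`.
#' @export
extract_contour <- function(mask, pixel_size, smooth_window = 5) {
  mask <- mask != 0
  stopifnot(pixel_size > 0)
  if (!any(mask)) stop("empty mask: no contour", call. = FALSE)
  lab <- as_matrix(EBImage::bwlabel(ebi(mask * 1)))
  if (max(lab) > 1) {
    warning("multiple components: largest taken")
    counts <- tabulate(lab[lab > 0])
    mask <- lab == which.max(counts)
  }
  filled <- as_matrix(EBImage::fillHull(ebi(mask * 1))) > 0
  if (sum(filled) > sum(mask)) warning("holes in mask filled")
  mask <- filled
  if (sum(mask) < 100) stop("component smaller than 100 pixels", call. = FALSE)
  # contourLines wants z[i, j] at (x[i], y[j]); our rows are y, so pass the
  # transpose-free matrix and swap the outputs.
  nr <- nrow(mask); nc <- ncol(mask)
  cl <- grDevices::contourLines(x = (seq_len(nr) - 1), y = (seq_len(nc) - 1),
                                z = mask * 1, levels = 0.5)
  if (length(cl) == 0) stop("no contour found", call. = FALSE)
  lengths <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lengths)]]
  X <- cc$y * pixel_size   # columns -> x
  Y <- cc$x * pixel_size   # rows    -> y
  # drop duplicated closing vertex if present
  n <- length(X)
  if (X[1] == X[n] && Y[1] == Y[n]) { X <- X[-n]; Y <- Y[-n] }
  if (length(X) < 20) stop("contour has fewer than 20 vertices", call. = FALSE)
  # enforce counter-clockwise orientation in (x right, y up) sense
  if (pracma::polyarea(X, Y) < 0) { X <- rev(X); Y <- rev(Y) }
  if (smooth_window > 1) {
    X <- circular_ma(X, smooth_window)
    Y <- circular_ma(Y, smooth_window)
  }
  # resample uniformly in arclength (~1 px spacing) so that downstream
  # filters and windows in arclength act uniformly
  ds0 <- sqrt(diff(c(X, X[1]))^2 + diff(c(Y, Y[1]))^2)
  s0 <- c(0, cumsum(ds0))
  n_out <- max(20, round(s0[length(s0)] / pixel_size))
  su <- seq(0, s0[length(s0)], length.out = n_out + 1)[-(n_out + 1)]
  X <- approx(s0, c(X, X[1]), su)$y
  Y <- approx(s0, c(Y, Y[1]), su)$y
  ds <- sqrt(diff(c(X, X[1]))^2 + diff(c(Y, Y[1]))^2)
  idx <- which(mask, arr.ind = TRUE)
  structure(list(x = X, y = Y,
                 s = c(0, cumsum(ds))[seq_along(X)],
                 perimeter_um = sum(ds),
                 centroid = c(mean(X), mean(Y)),
                 center = c((mean(idx[, 2]) - 1) * pixel_size,
                            (mean(idx[, 1]) - 1) * pixel_size),
                 area_um2 = sum(mask) * pixel_size^2,
                 pixel_size = pixel_size,
                 smooth_window = smooth_window),
            class = "droplet_contour")
}

# Keep the `keep` lowest harmonics of a circular signal (plus the mean).
fourier_lowpass <- function(v, keep) {
  n <- length(v)
  if (2 * keep + 1 >= n) return(v)
  f <- fft(v)
  idx <- seq_len(n) - 1
  hz <- pmin(idx, n - idx)               # harmonic number of each bin
  f[hz > keep] <- 0
  Re(fft(f, inverse = TRUE)) / n
}

circular_ma <- function(v, w) {
  k <- (w - 1) %/% 2
  n <- length(v)
  ext <- c(tail(v, k), v, head(v, k))
  as.numeric(stats::filter(ext, rep(1 / w, w), sides = 2))[(k + 1):(k + n)]
}

# Exact minimum enclosing circle (Welzl's algorithm, randomized,
# move-to-front) over a set of 2-D points.
min_enclosing_circle <- function(x, y) {
  pts <- cbind(x, y)
  n <- nrow(pts)
  circ2 <- function(a, b) {
    c(ctr = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c3) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c3[1]; cy <- c3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    ctr <- c(ux, uy)
    c(ctr, sqrt(sum((a - ctr)^2)))
  }
  inside <- function(circ, p) {
    !is.null(circ) && sqrt(sum((p - circ[1:2])^2)) <= circ[3] * (1 + 1e-10)
  }
  ord <- with_seed(1234, sample.int(n))  # deterministic shuffle
  circ <- c(0, 0, -1)
  for (ii in seq_len(n)) {
    p <- pts[ord[ii], ]
    if (inside(circ, p)) next
    circ <- c(p, 0)
    for (jj in seq_len(ii - 1)) {
      q <- pts[ord[jj], ]
      if (inside(circ, q)) next
      cc <- circ2(p, q); circ <- c(cc[1], cc[2], cc[3])
      for (kk in seq_len(jj - 1)) {
        r <- pts[ord[kk], ]
        if (inside(circ, r)) next
        circ <- circ3(p, q, r) %||% circ
      }
    }
  }
  list(center = unname(circ[1:2]), radius = unname(circ[3]))
}

#' Droplet sphericity from inscribed and circumscribed circles
#'
#' `D_in` is twice the maximum of the interior Euclidean distance transform;
#' `D_out` is the diameter of the exact minimum enclosing circle of the
#' contour vertices; sphericity is their ratio, and a droplet is flagged
#' spherical when the ratio strictly exceeds `threshold`.
#'
#' @param mask binary droplet mask.
#' @param contour a [extract_contour()] result (computed from `mask` when
#'   omitted).
#' @param pixel_size um per pixel.
#' @param threshold sphericity flag threshold (default 0.8).
#' @return list of class `shape_metrics`: `D_in_um`, `D_out_um`,
#'   `sphericity`, `spherical`, `solidity`.
#' @export
sphericity <- function(mask, pixel_size, contour = NULL, threshold = 0.8) {
  mask <- mask != 0
  contour <- contour %||% extract_contour(mask, pixel_size)
  dt <- as_matrix(EBImage::distmap(ebi(mask * 1)))
  D_in <- 2 * max(dt) * pixel_size
  mec <- min_enclosing_circle(contour$x, contour$y)
  D_out <- 2 * mec$radius
  sph <- D_in / D_out
  structure(list(D_in_um = D_in, D_out_um = D_out, sphericity = sph,
                 spherical = sph > threshold,
                 solidity = solidity(mask),
                 out_center = mec$center),
            class = "shape_metrics")
}

#' Solidity: area over convex-hull area
#'
#' Component pixel area divided by the area of the convex hull of the pixel
#' corner points (so a convex shape scores 1 up to pixelation).
#'
#' @param mask binary mask (largest component used).
#' @return solidity in `(0, 1]`.
#' @export
solidity <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  lab <- as_matrix(EBImage::bwlabel(ebi(mask * 1)))
  if (max(lab) > 1) {
    counts <- tabulate(lab[lab > 0])
    mask <- lab == which.max(counts)
  }
  idx <- which(mask, arr.ind = TRUE)
  # pixel corners: centers +- 1/2 in both axes
  xs <- c(idx[, 2] - 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] + 0.5)
  ys <- c(idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5)
  h <- chull(xs, ys)
  hull_area <- abs(pracma::polyarea(xs[h], ys[h]))
  sum(mask) / hull_area
}

# Least-squares (Kasa) circle fit; returns center, radius, rms residual.
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  ctr <- sol[1:2]
  r <- sqrt(sol[3] + sum(ctr^2))
  list(center = ctr, radius = r,
       rms = sqrt(mean((sqrt((x - ctr[1])^2 + (y - ctr[2])^2) - r)^2)))
}

#' Local curvature profile along a droplet contour
#'
#' Local curvature at each vertex comes from a least-squares circle fit over
#' a sliding window; the global curvature `kappa0` from a single circle fit
#' to the whole contour. The reported profile is `|kappa| / kappa0`.
#'
#' @param contour a [extract_contour()] result.
#' @param window window size in um (default 10% of the perimeter); must span
#'   at least 5 vertex spacings.
#' @return data.frame of class `curvature_profile` with columns `s_um`,
#'   `kappa`, `ratio`; `kappa0` and the window are attached as attributes.
#' @export
local_curvature <- function(contour, window = NULL) {
  stopifnot(inherits(contour, "droplet_contour"))
  n <- length(contour$x)
  window <- window %||% (0.1 * contour$perimeter_um)
  spacing <- contour$perimeter_um / n
  if (window < 5 * spacing)
    stop("curvature window must span at least 5 vertex spacings", call. = FALSE)
  half <- max(2, round(window / spacing / 2))
  g <- fit_circle(contour$x, contour$y)
  kappa0 <- 1 / g$radius
  # suppress pixel-quantization waviness below the analysis window: keep
  # only Fourier harmonics of the closed contour with wavelength >= window
  keep <- max(4, ceiling(contour$perimeter_um / window))
  cx <- fourier_lowpass(contour$x, keep)
  cy <- fourier_lowpass(contour$y, keep)
  kap <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - half):(i + half) - 1) %% n + 1
    f <- fit_circle(cx[idx], cy[idx])
    if (is.null(f) || !is.finite(f$radius) || f$radius <= 0) {
      kap[i] <- 0
    } else {
      # sign from turning direction of the window end points about the vertex
      a <- c(cx[idx[1]], cy[idx[1]])
      m <- c(cx[i], cy[i])
      b <- c(cx[idx[length(idx)]], cy[idx[length(idx)]])
      cr <- (m[1] - a[1]) * (b[2] - m[2]) - (m[2] - a[2]) * (b[1] - m[1])
      kap[i] <- sign(cr) / f$radius
    }
  }
  out <- data.frame(s_um = contour$s, kappa = kap, ratio = abs(kap) * g$radius)
  attr(out, "kappa0") <- kappa0
  attr(out, "window_um") <- window
  class(out) <- c("curvature_profile", "data.frame")
  out
}

#' Sphericity-versus-size threshold fit
#'
#' Fits a logistic in log droplet size to the sphericity values and reports
#' the size at which the fitted curve crosses `threshold` (the size below
#' which droplets deform).
#'
#' @param metrics data.frame with columns `D_in_um` and `sphericity`
#'   (>= 10 droplets).
#' @param threshold sphericity level defining the crossing (default 0.8).
#' @return list with `threshold_size_um` (numeric, or `-Inf` when the whole
#'   fitted curve stays above `threshold`), `fit` and `residuals`.
#' @export
sphericity_vs_size <- function(metrics, threshold = 0.8) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 10,
            all(c("D_in_um", "sphericity") %in% names(metrics)))
  ld <- log(metrics$D_in_um)
  sph <- metrics$sphericity
  lo <- max(min(sph), 1e-3); hi <- max(sph)
  start <- list(smin = lo, smax = hi, mid = median(ld), w = 0.3)
  fit <- tryCatch(
    minpack.lm::nlsLM(sph ~ smin + (smax - smin) / (1 + exp(-(ld - mid) / w)),
                      start = start,
                      lower = c(0, 0, min(ld) - 5, 0.01),
                      upper = c(1.2, 1.2, max(ld) + 5, 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (e.g. all-spherical) populations: no crossing observable
    thr <- if (all(sph > threshold)) -Inf else min(metrics$D_in_um)
    return(list(threshold_size_um = thr, fit = NULL, residuals = NULL))
  }
  cf <- as.list(coef(fit))
  pred <- function(l) cf$smin + (cf$smax - cf$smin) / (1 + exp(-(l - cf$mid) / cf$w))
  grid <- seq(min(ld) - 2, max(ld) + 2, length.out = 2000)
  pv <- pred(grid)
  thr <- if (all(pv > threshold)) {
    -Inf  # below every observed size
  } else if (all(pv < threshold)) {
    Inf
  } else {
    cross <- which(pv[-1] > threshold & pv[-length(pv)] <= threshold)
    if (length(cross) == 0) -Inf
    else exp(approx(pv[c(cross[1], cross[1] + 1)],
                    grid[c(cross[1], cross[1] + 1)], threshold)$y)
  }
  list(threshold_size_um = thr, fit = fit, residuals = residuals(fit))
}
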