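# Bending-stiffness estimation from thermal shape fluctuations.
#
# A fluctuating semiflexible filament with free ends is decomposed into
# bending eigenmodes; equipartition fixes the variance of each mode
# amplitude, var(a_q) = k_B T / (kappa q^4), so the q-dependence of the
# measured amplitude variances yields the bending stiffness kappa and the
# persistence length L_p = kappa / (k_B T).

#' Construct a filament backbone
#'
#' @param x,y ordered backbone coordinates in um.
#' @param frame optional frame index.
#' @return object of class `backbone` with fields `x`, `y`, `s` (arclength,
#'   um), `L` (contour length, um) and `frame`.
#' @export
backbone <- function(x, y, frame = NA_integer_) {
  stopifnot(length(x) == length(y), length(x) >= 10)
  ds <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(ds <= 0))
    stop("backbone has duplicate consecutive points", call. = FALSE)
  s <- c(0, cumsum(ds))
  structure(list(x = x, y = y, s = s, L = s[length(s)], frame = frame),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d points, L = %.3f um, frame %s\n",
              length(x$x), x$L, x$frame))
  invisible(x)
}

#' Local tangent angles along a backbone
#'
#' theta_i = atan2(y_{i+1} - y_i, x_{i+1} - x_i), unwrapped to remove +-pi
#' jumps; the angle is attributed to the midpoint arclength of each segment.
#'
#' @param bb a [backbone()].
#' @return list with `s` (midpoint arclengths, um) and `theta` (rad,
#'   unwrapped).
#' @export
tangent_angles <- function(bb) {
  stopifnot(inherits(bb, "backbone"))
  dx <- diff(bb$x); dy <- diff(bb$y)
  if (any(dx == 0 & dy == 0))
    stop("duplicate consecutive points in backbone", call. = FALSE)
  theta <- atan2(dy, dx)
  # unwrap
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta <- theta - 2 * pi * jumps
  list(s = (bb$s[-1] + bb$s[-length(bb$s)]) / 2, theta = theta)
}

#' Project tangent angles onto bending modes (one frame)
#'
#' Computes the mode amplitudes `a_q = -integral theta(s) ytilde_q(s) ds`
#' (trapezoid rule) for modes `k = 1..k_max`. The per-frame mean tangent
#' angle is subtracted first, which removes the rigid-body rotation exactly
#' for every mode; in the small-slope regime the amplitudes equal the
#' projection of the transverse deflection onto the eigenfunctions.
#'
#' @param theta tangent angles (rad) on an increasing arclength grid.
#' @param s arclength positions of `theta` (um), spanning `[0, L]` up to half
#'   a sampling step at each end.
#' @param L contour length (um).
#' @param k_max highest mode, at most 10.
#' @param convention eigenvalue convention, see [mode_alpha()].
#' @return object of class `mode_spectrum`: list with `k`, `q` (1/um) and
#'   amplitudes `a` (um^(3/2)).
#' @export
mode_amplitudes <- function(theta, s, L, k_max = 4,
                            convention = c("exact", "half_integer_pi", "printed")) {
  convention <- match.arg(convention)
  if (k_max > 10) stop("k_max > 10 exceeds the mode resolution limit", call. = FALSE)
  stopifnot(length(theta) == length(s), all(diff(s) > 0), L > 0)
  th <- theta - mean(theta)
  if (max(abs(th)) > 0.35)
    warning("tangent-angle excursion > 0.35 rad: small-slope assumption strained")
  ks <- seq_len(k_max)
  a <- vapply(ks, function(k) {
    ef <- eigenfunctions(k, L, s, convention)
    -pracma::trapz(s, th * ef$ytilde)
  }, numeric(1))
  q <- mode_alpha(ks, convention) / L
  structure(list(k = ks, q = q, a = a), class = "mode_spectrum")
}

#' Mode-amplitude table for an ensemble of backbones
#'
#' @param backbones list of [backbone()] objects (frames of one filament).
#' @param k_max highest mode.
#' @param L contour length used for the eigenfunctions; defaults to the
#'   median traced length across frames.
#' @inheritParams mode_amplitudes
#' @return list with `L`, `k`, `q` and the frames-by-modes amplitude matrix
#'   `amplitudes`.
#' @export
backbone_spectra <- function(backbones, k_max = 4, L = NULL,
                             convention = c("exact", "half_integer_pi", "printed")) {
  convention <- match.arg(convention)
  stopifnot(length(backbones) >= 1)
  L <- L %||% median(vapply(backbones, function(b) b$L, numeric(1)))
  amps <- t(vapply(backbones, function(b) {
    ta <- tangent_angles(b)
    # map this frame's arclength onto the common [0, L] grid
    sc <- ta$s * (L / b$L)
    mode_amplitudes(ta$theta, sc, L, k_max, convention)$a
  }, numeric(k_max)))
  ks <- seq_len(k_max)
  list(L = L, k = ks, q = mode_alpha(ks, convention) / L, amplitudes = amps)
}

#' Bending stiffness from mode-amplitude variances
#'
#' Equipartition gives `var(a_q) = k_B T / (kappa q^4)`. The fit is performed
#' in log-log with the exponent fixed at -4 (intercept-only least squares);
#' a freely fitted exponent is reported as a diagnostic.
#'
#' @param spectra result of [backbone_spectra()], or any list with fields
#'   `q` and `amplitudes` (frames x modes).
#' @param temperature kelvin.
#' @param fit_modes indices of the modes entering the fit (>= 2 modes).
#' @return object of class `stiffness_estimate`: `kappa` (pN um^2),
#'   `persistence_length` (um), `var_aq`, `q`, `fit_modes`, `n_frames`,
#'   `free_exponent` (diagnostic) and `r_squared` of the fixed-slope fit.
#' @export
estimate_kappa <- function(spectra, temperature = 293,
                           fit_modes = seq_along(spectra$q)) {
  stopifnot(is.matrix(spectra$amplitudes))
  if (length(fit_modes) < 2)
    stop("stiffness fit needs at least 2 modes", call. = FALSE)
  if (!all(fit_modes %in% seq_along(spectra$q)))
    stop("fit_modes outside the computed mode range", call. = FALSE)
  n_frames <- nrow(spectra$amplitudes)
  v <- apply(spectra$amplitudes, 2, var)
  if (any(v[fit_modes] == 0))
    stop("zero amplitude variance: rigid filament or duplicated frames",
         call. = FALSE)
  q <- spectra$q[fit_modes]
  lv <- log(v[fit_modes])
  # fixed slope -4: log var = log(kBT/kappa) - 4 log q
  intercept <- mean(lv + 4 * log(q))
  kappa <- kBT(temperature) / exp(intercept)
  free <- lm(lv ~ log(q))
  resid_fixed <- lv - (intercept - 4 * log(q))
  r2 <- if (length(lv) > 2 && var(lv) > 0) 1 - sum(resid_fixed^2) / sum((lv - mean(lv))^2) else NA_real_
  structure(list(kappa = kappa,
                 persistence_length = kappa / kBT(temperature),
                 var_aq = v, q = spectra$q, fit_modes = fit_modes,
                 n_frames = n_frames,
                 free_exponent = unname(coef(free)[2]),
                 r_squared = r2),
            class = "stiffness_estimate")
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat(sprintf("<stiffness_estimate> kappa = %.4g pN um^2, L_p = %.4g um (%d frames, modes %s)\n",
              x$kappa, x$persistence_length, x$n_frames,
              paste(x$fit_modes, collapse = ",")))
  cat(sprintf("  freely fitted exponent: %.3f (fixed at -4 in the fit)\n",
              x$free_exponent))
  invisible(x)
}

#' Trace a filament backbone from a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), orders the skeleton pixels
#' end to end along the longest geodesic path, smooths x(s) and y(s) with a
#' smoothing spline and resamples at uniform arclength.
#'
#' @param mask logical/0-1 matrix containing exactly one 8-connected
#'   filamentous component.
#' @param pixel_size um per pixel.
#' @param n_points number of resampled backbone points.
#' @param spar smoothing parameter passed to [stats::smooth.spline()].
#' @return a [backbone()] in um coordinates.
#' @export
trace_backbone <- function(mask, pixel_size, n_points = 100, spar = 0.4) {
  mask <- mask != 0
  stopifnot(pixel_size > 0)
  lab <- as_matrix(EBImage::bwlabel(ebi(mask * 1)))
  ncomp <- max(lab)
  if (ncomp == 0) stop("empty mask", call. = FALSE)
  if (ncomp > 1) stop(ncomp, " connected components in mask; expected one",
                      call. = FALSE)
  sk <- thin_mask(mask)
  g <- skeleton_graph(sk)
  deg <- igraph::degree(g$graph)
  if (any(deg > 2)) {
    bp <- g$pixels[deg > 2, , drop = FALSE]
    stop("branched skeleton; branch points at (row, col): ",
         paste(apply(bp, 1, paste, collapse = ","), collapse = "; "),
         call. = FALSE)
  }
  path <- skeleton_longest_path(g)
  # 0-based pixel centers in um: x = (col-1)*px, y = (row-1)*px
  px <- (g$pixels[path, 2] - 1) * pixel_size
  py <- (g$pixels[path, 1] - 1) * pixel_size
  if (length(px) < 4) stop("skeleton too short to trace", call. = FALSE)
  s <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  fx <- smooth.spline(s, px, spar = spar)
  fy <- smooth.spline(s, py, spar = spar)
  ss <- seq(0, max(s), length.out = max(n_points, 10))
  xs <- predict(fx, ss)$y; ys <- predict(fy, ss)$y
  # thinning stops short of each filament tip; extend both ends along the
  # local tangent until the extension leaves the mask
  n <- length(xs)
  ext <- function(i_end, i_in) {
    tx <- xs[i_end] - xs[i_in]; ty <- ys[i_end] - ys[i_in]
    nrm <- sqrt(tx^2 + ty^2)
    tx <- tx / nrm; ty <- ty / nrm
    step <- 0.25 * pixel_size
    d <- 0
    repeat {
      xn <- xs[i_end] + (d + step) * tx; yn <- ys[i_end] + (d + step) * ty
      i <- round(yn / pixel_size) + 1; j <- round(xn / pixel_size) + 1
      if (i < 1 || j < 1 || i > nrow(mask) || j > ncol(mask) || !mask[i, j])
        break
      d <- d + step
    }
    c(xs[i_end] + d * tx, ys[i_end] + d * ty)
  }
  p0 <- ext(1, min(5, n))
  p1 <- ext(n, max(n - 4, 1))
  xs <- c(p0[1], xs, p1[1]); ys <- c(p0[2], ys, p1[2])
  # resample at uniform arclength of the smoothed, extended curve
  s2 <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  su <- seq(0, max(s2), length.out = max(n_points, 10))
  backbone(approx(s2, xs, su)$y, approx(s2, ys, su)$y)
}

#' Read backbones from a long-format CSV
#'
#' Expected columns: `frame`, `point`, `x_um`, `y_um`.
#' @param path CSV path.
#' @return list of [backbone()] objects ordered by frame.
#' @export
read_backbones <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("frame", "point", "x_um", "y_um") %in% names(d)))
  lapply(split(d, d$frame), function(f) {
    f <- f[order(f$point), ]
    backbone(f$x_um, f$y_um, frame = f$frame[1])
  })
}

#' Write backbones to a long-format CSV
#' @param backbones list of [backbone()] objects.
#' @param path output CSV path.
#' @export
write_backbones <- function(backbones, path) {
  d <- do.call(rbind, lapply(seq_along(backbones), function(i) {
    b <- backbones[[i]]
    data.frame(frame = if (is.na(b$frame)) i else b$frame,
               point = seq_along(b$x), x_um = b$x, y_um = b$y)
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
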