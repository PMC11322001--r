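# Synthetic-data generators. Every generator is a pure function of
# (parameters, seed) and returns its ground truth alongside the data, so each
# analysis stage can be tested by parameter recovery instead of experimental
# data.

#' Scene configuration for rendered images
#'
#' @param image_shape `(height, width)` in pixels.
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian PSF sigma in um (0 disables blurring).
#' @param background_level background intensity (a.u.).
#' @param noise_sd Gaussian read-noise SD (a.u.).
#' @param seed integer RNG seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(512, 512), pixel_size = 0.2,
                         psf_sigma = 0.2, background_level = 10,
                         noise_sd = 2, seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1),
            pixel_size > 0, psf_sigma >= 0, noise_sd >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = seed),
            class = "scene_config")
}

#' Ground-truth parameters of a fluctuating filament
#'
#' @param L contour length (um).
#' @param kappa bending stiffness (pN um^2).
#' @param temperature kelvin.
#' @param k_max number of thermally excited modes (<= 10).
#' @param frames number of statistically independent frames.
#' @param n_points backbone points per frame.
#' @return object of class `filament_truth` (backbones empty until
#'   [gen_fluctuating_filament()] is called).
#' @export
filament_truth <- function(L = 6, kappa = 0.04, temperature = 293,
                           k_max = 4, frames = 500, n_points = 100) {
  if (L <= 0) stop("filament length must be positive", call. = FALSE)
  if (kappa <= 0) stop("bending stiffness must be positive", call. = FALSE)
  stopifnot(k_max >= 1, k_max <= 10, frames >= 1, n_points >= 10)
  structure(list(L = L, kappa = kappa, temperature = temperature,
                 k_max = k_max, frames = frames, n_points = n_points,
                 backbones = NULL),
            class = "filament_truth")
}

#' Generate thermally fluctuating filament backbones
#'
#' For each frame, mode amplitudes `a_q` are drawn independently from a
#' zero-mean normal law with the equipartition variance
#' `k_B T / (kappa q^4)`. The backbone is built by integrating the
#' tangent-angle field `theta(s) = sum_q a_q y'_q(s)` of the transverse
#' deflection `u(s) = sum_q a_q y_q(s)` about a straight baseline:
#' `x(s) = integral cos(theta)`, `y(s) = integral sin(theta)`. This imposes
#' the contour length L exactly (the filament is inextensible by
#' construction) and reduces to baseline-plus-deflection in the small-slope
#' limit.
#'
#' @param truth a [filament_truth()].
#' @param seed integer seed.
#' @param convention eigenvalue convention, see [mode_alpha()].
#' @return the `filament_truth` with `backbones` (list of [backbone()]) and
#'   the drawn `amplitudes` matrix (frames x modes) filled in.
#' @export
gen_fluctuating_filament <- function(truth, seed = 1,
                                     convention = c("exact", "half_integer_pi", "printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(truth, "filament_truth"))
  L <- truth$L
  s <- seq(0, L, length.out = truth$n_points)
  Yp <- vapply(seq_len(truth$k_max),
               function(k) eigenfunctions(k, L, s, convention)$yprime,
               numeric(length(s)))
  q <- mode_alpha(seq_len(truth$k_max), convention) / L
  sdev <- sqrt(kBT(truth$temperature) / (truth$kappa * q^4))
  ds <- diff(s)
  with_seed(seed, {
    amps <- matrix(rnorm(truth$frames * truth$k_max), truth$frames) *
      rep(sdev, each = truth$frames)
    truth$amplitudes <- amps
    truth$backbones <- lapply(seq_len(truth$frames), function(f) {
      theta <- as.numeric(Yp %*% amps[f, ])
      # integrate the unit tangent (trapezoid): arclength is exactly L
      cmid <- (cos(theta)[-1] + cos(theta)[-length(theta)]) / 2
      smid <- (sin(theta)[-1] + sin(theta)[-length(theta)]) / 2
      x <- c(0, cumsum(cmid * ds))
      y <- c(0, cumsum(smid * ds))
      backbone(x, y, frame = f)
    })
  })
  truth
}

# ---- scene rendering --------------------------------------------------------

# Pixel-center coordinate grids in um (0-based centers).
scene_grids <- function(config) {
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  list(X = matrix(rep((seq_len(nc) - 1) * config$pixel_size, each = nr), nr),
       Y = matrix(rep((seq_len(nr) - 1) * config$pixel_size, nc), nr))
}

rasterize_object <- function(obj, config, grids) {
  X <- grids$X; Y <- grids$Y
  amp <- obj$amplitude %||% 100
  layer <- matrix(0, nrow(X), ncol(X))
  px <- config$pixel_size
  # anti-aliased coverage from the signed inside-distance m (um): full
  # intensity one pixel inside the boundary, linear ramp across it
  cov_ramp <- function(m) pmin(pmax(0.5 + m / px, 0), 1)
  switch(obj$type,
    disk = {
      r <- sqrt((X - obj$x)^2 + (Y - obj$y)^2)
      layer <- amp * cov_ramp(obj$radius - r)
    },
    shell = {
      r <- sqrt((X - obj$x)^2 + (Y - obj$y)^2)
      th <- obj$thickness %||% (0.1 * obj$radius)
      layer <- amp * cov_ramp(pmin(obj$radius - r, r - (obj$radius - th)))
    },
    rect = ,
    spindle = {
      u <- (X - obj$x) * cos(obj$orientation) + (Y - obj$y) * sin(obj$orientation)
      v <- -(X - obj$x) * sin(obj$orientation) + (Y - obj$y) * cos(obj$orientation)
      half <- if (obj$type == "rect") obj$width / 2
              else (obj$width / 2) * sin(pi * pmin(pmax(u / obj$length + 0.5, 0), 1))
      layer <- amp * cov_ramp(pmin(half - abs(v), obj$length / 2 - abs(u)))
    },
    filament = {
      # deposit intensity along the polyline, ~4 samples per pixel
      step <- config$pixel_size / 4
      seg <- sqrt(diff(obj$x_coords)^2 + diff(obj$y_coords)^2)
      stot <- c(0, cumsum(seg))
      su <- seq(0, max(stot), by = step)
      xs <- approx(stot, obj$x_coords, su)$y
      ys <- approx(stot, obj$y_coords, su)$y
      jj <- round(xs / config$pixel_size) + 1
      ii <- round(ys / config$pixel_size) + 1
      ok <- ii >= 1 & ii <= nrow(layer) & jj >= 1 & jj <= ncol(layer)
      for (t in which(ok))
        layer[ii[t], jj[t]] <- layer[ii[t], jj[t]] + amp
    },
    stop("unknown object type: ", obj$type, call. = FALSE)
  )
  layer
}

truth_row <- function(id, obj) {
  data.frame(id = id, type = obj$type,
             x_um = obj$x %||% NA_real_, y_um = obj$y %||% NA_real_,
             length_um = obj$length %||% NA_real_,
             width_um = obj$width %||% NA_real_,
             radius_um = obj$radius %||% NA_real_,
             orientation_rad = obj$orientation %||% NA_real_,
             amplitude = obj$amplitude %||% 100)
}

#' Render a synthetic fluorescence scene
#'
#' Rasterizes placed objects (disks, shells, rectangles, spindle-shaped
#' tactoids, filament polylines) onto a background, applies a Gaussian PSF
#' and adds Gaussian read noise. Every object is recorded in a ground-truth
#' table.
#'
#' @param config a [scene_config()].
#' @param objects list of object specs; each is a list with a `type` field
#'   (`"disk"`, `"shell"`, `"rect"`, `"spindle"`, `"filament"`) and type-specific
#'   geometry in um (`x`, `y`, `radius`, `length`, `width`, `orientation`,
#'   `thickness`, `x_coords`/`y_coords`, `amplitude`).
#' @return object of class `scene`: list with `image` (matrix, rows = y),
#'   `truth` (data.frame) and `config`.
#' @export
render_scene <- function(config, objects = list()) {
  stopifnot(inherits(config, "scene_config"))
  if (length(objects) == 0)
    warning("empty object list: rendering background-only scene")
  grids <- scene_grids(config)
  img <- matrix(0, config$image_shape[1], config$image_shape[2])
  truth <- NULL
  for (i in seq_along(objects)) {
    img <- img + rasterize_object(objects[[i]], config, grids)
    truth <- rbind(truth, truth_row(i, objects[[i]]))
  }
  if (config$psf_sigma > 0 && length(objects) > 0) {
    sig_px <- config$psf_sigma / config$pixel_size
    img <- as_matrix(EBImage::gblur(ebi(img), sigma = sig_px))
  }
  img <- img + config$background_level
  if (config$noise_sd > 0)
    img <- img + with_seed(config$seed,
                           matrix(rnorm(length(img), 0, config$noise_sd),
                                  nrow(img)))
  structure(list(image = img,
                 truth = truth %||% data.frame(),
                 config = config),
            class = "scene")
}

# ---- trajectories -----------------------------------------------------------

#' Ground-truth kinetic parameters
#'
#' @param D_free free diffusion coefficient (um^2/s).
#' @param cage_radius confinement radius of trapped particles (um); the
#'   long-lag MSD of a trapped particle plateaus near `cage_radius^2`.
#' @param k release rate (1/time-unit).
#' @param bleach_factor multiplicative intensity loss per acquisition, (0, 1].
#' @param I0 initial intensity (a.u.).
#' @param Iinf plateau intensity (a.u.).
#' @return object of class `kinetics_truth`.
#' @export
kinetics_truth <- function(D_free = 0.31, cage_radius = 0.3, k = 0.05,
                           bleach_factor = 1, I0 = 100, Iinf = 10) {
  stopifnot(D_free >= 0, cage_radius >= 0, k >= 0,
            bleach_factor > 0, bleach_factor <= 1, I0 >= Iinf, Iinf >= 0)
  structure(list(D_free = D_free, cage_radius = cage_radius, k = k,
                 bleach_factor = bleach_factor, I0 = I0, Iinf = Iinf),
            class = "kinetics_truth")
}

#' Generate 2-D Brownian and caged trajectories
#'
#' Free particles take independent Gaussian steps with per-axis variance
#' `2 D dt`; trapped particles follow a stationary Ornstein-Uhlenbeck process
#' in a harmonic cage whose per-axis stationary SD is `cage_radius / 2`, so
#' the total long-lag MSD plateau is `cage_radius^2`.
#'
#' @param truth a [kinetics_truth()].
#' @param n_particles number of particles.
#' @param n_steps number of steps (>= 10).
#' @param dt frame interval (s).
#' @param trapped_fraction fraction of trapped particles in `[0, 1]`.
#' @param arena side length (um) of the square over which starting positions
#'   (cage centres for trapped particles) are spread uniformly.
#' @param seed integer seed.
#' @return data.frame with columns `particle`, `t`, `x_um`, `y_um`,
#'   `true_class` (`"diffusive"` or `"trapped"`).
#' @export
gen_trajectories <- function(truth, n_particles = 100, n_steps = 100,
                             dt = 1, trapped_fraction = 0, arena = 50,
                             seed = 1) {
  stopifnot(inherits(truth, "kinetics_truth"), dt > 0, n_steps >= 10)
  if (trapped_fraction < 0 || trapped_fraction > 1)
    stop("trapped_fraction must lie in [0, 1]", call. = FALSE)
  n_trap <- round(n_particles * trapped_fraction)
  cls <- rep(c("trapped", "diffusive"),
             c(n_trap, n_particles - n_trap))
  sigma_cage <- truth$cage_radius / 2
  tau <- if (truth$D_free > 0 && sigma_cage > 0)
    sigma_cage^2 / truth$D_free else Inf
  with_seed(seed, {
    out <- lapply(seq_len(n_particles), function(p) {
      x0 <- runif(1, 0, arena); y0 <- runif(1, 0, arena)
      if (cls[p] == "diffusive") {
        sd_step <- sqrt(2 * truth$D_free * dt)
        x <- x0 + c(0, cumsum(rnorm(n_steps, 0, sd_step)))
        y <- y0 + c(0, cumsum(rnorm(n_steps, 0, sd_step)))
      } else if (is.finite(tau)) {
        a <- exp(-dt / tau)
        innov_sd <- sigma_cage * sqrt(1 - a^2)
        x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
        x[1] <- rnorm(1, 0, sigma_cage); y[1] <- rnorm(1, 0, sigma_cage)
        for (t in seq_len(n_steps)) {
          x[t + 1] <- a * x[t] + rnorm(1, 0, innov_sd)
          y[t + 1] <- a * y[t] + rnorm(1, 0, innov_sd)
        }
        x <- x + x0; y <- y + y0
      } else {
        x <- rep(x0, n_steps + 1); y <- rep(y0, n_steps + 1)
      }
      data.frame(particle = p, t = (0:n_steps) * dt, x_um = x, y_um = y,
                 true_class = cls[p])
    })
    do.call(rbind, out)
  })
}

#' Generate a release-intensity time series with photobleaching
#'
#' Observed intensity at frame i (time `t_i`) is
#' `[Iinf + (I0 - Iinf) exp(-k t_i)] * bleach_factor^i + noise`; a matched
#' no-release control (k = 0) with the same bleach factor is returned for
#' photobleach calibration.
#'
#' @param truth a [kinetics_truth()].
#' @param n_frames number of frames (used when `frame_times` is NULL).
#' @param frame_times strictly increasing acquisition times; defaults to
#'   `0:(n_frames-1)`.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param seed integer seed.
#' @return list with `times`, `release`, `control` and `truth`.
#' @export
gen_release_series <- function(truth, n_frames = 20, frame_times = NULL,
                               noise_sd = 0, seed = 1) {
  stopifnot(inherits(truth, "kinetics_truth"))
  times <- frame_times %||% (seq_len(n_frames) - 1)
  if (any(diff(times) <= 0))
    stop("frame_times must be strictly increasing", call. = FALSE)
  i <- seq_along(times) - 1
  clean <- (truth$Iinf + (truth$I0 - truth$Iinf) * exp(-truth$k * times)) *
    truth$bleach_factor^i
  ctrl <- truth$I0 * truth$bleach_factor^i
  with_seed(seed, {
    noise1 <- rnorm(length(times), 0, noise_sd)
    noise2 <- rnorm(length(times), 0, noise_sd)
    list(times = times, release = clean + noise1, control = ctrl + noise2,
         truth = truth)
  })
}

#' Generate a smooth inhomogeneous illumination field
#'
#' A random low-order polynomial surface rescaled to mean exactly 1 and
#' range within `[1 - amplitude, 1 + amplitude]`.
#'
#' @param config a [scene_config()] (shape and seed are used).
#' @param gradient_amplitude relative amplitude in `[0, 1)`.
#' @return matrix with mean 1.
#' @export
gen_illumination_field <- function(config, gradient_amplitude = 0.2) {
  stopifnot(inherits(config, "scene_config"),
            gradient_amplitude >= 0, gradient_amplitude < 1)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  if (gradient_amplitude == 0) return(matrix(1, nr, nc))
  X <- matrix(rep(seq(-1, 1, length.out = nc), each = nr), nr)
  Y <- matrix(rep(seq(-1, 1, length.out = nr), nc), nr)
  cf <- with_seed(config$seed, runif(5, -1, 1))
  raw <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 + cf[5] * Y^2
  raw <- raw - mean(raw)
  raw <- raw * (gradient_amplitude / max(abs(raw)))
  1 + raw
}
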