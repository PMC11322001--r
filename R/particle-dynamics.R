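# Payload particle dynamics: detection linking, time-averaged mean-square
# displacement, trapped/diffusive classification and diffusion-coefficient
# fitting, with the Stokes-Einstein prediction as reference.

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour linking frame to frame with one-frame gap
#' closing; candidate links beyond `max_step` are rejected and start new
#' trajectories. Ambiguous ties are resolved by smallest displacement.
#'
#' @param detections data.frame with columns `t`, `x_um`, `y_um`.
#' @param max_step maximum link displacement per frame (um); gap-closed links
#'   may span up to `2 * max_step`.
#' @return data.frame `particle`, `t`, `x_um`, `y_um`.
#' @export
link_detections <- function(detections, max_step) {
  stopifnot(all(c("t", "x_um", "y_um") %in% names(detections)), max_step > 0)
  ts <- sort(unique(detections$t))
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_age <- integer(0)                     # frames since last seen
  next_id <- 1L
  rows <- vector("list", length(ts))
  for (fi in seq_along(ts)) {
    d <- detections[detections$t == ts[fi], , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(d))
    if (length(act_id) && nrow(d)) {
      cand <- expand.grid(ai = seq_along(act_id), di = seq_len(nrow(d)))
      cand$dist <- sqrt((act_x[cand$ai] - d$x_um[cand$di])^2 +
                          (act_y[cand$ai] - d$y_um[cand$di])^2)
      lim <- max_step * (1 + act_age[cand$ai])   # gap closing allowance
      cand <- cand[cand$dist <= lim, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_a <- logical(length(act_id)); used_d <- logical(nrow(d))
      for (r in seq_len(nrow(cand))) {
        ai <- cand$ai[r]; di <- cand$di[r]
        if (!used_a[ai] && !used_d[di]) {
          assigned[di] <- ai; used_a[ai] <- TRUE; used_d[di] <- TRUE
        }
      }
    }
    ids <- integer(nrow(d))
    for (di in seq_len(nrow(d))) {
      if (!is.na(assigned[di])) {
        ai <- assigned[di]
        ids[di] <- act_id[ai]
        act_x[ai] <- d$x_um[di]; act_y[ai] <- d$y_um[di]; act_age[ai] <- 0L
      } else {
        act_id <- c(act_id, next_id); act_x <- c(act_x, d$x_um[di])
        act_y <- c(act_y, d$y_um[di]); act_age <- c(act_age, 0L)
        ids[di] <- next_id; next_id <- next_id + 1L
      }
    }
    seen <- act_id %in% ids
    act_age[!seen] <- act_age[!seen] + 1L
    keep <- act_age <= 1L                    # allow one missed frame
    act_id <- act_id[keep]; act_x <- act_x[keep]
    act_y <- act_y[keep]; act_age <- act_age[keep]
    if (nrow(d))
      rows[[fi]] <- data.frame(particle = ids, t = d$t,
                               x_um = d$x_um, y_um = d$y_um)
  }
  out <- do.call(rbind, rows)
  out[order(out$particle, out$t), ]
}

#' Time-averaged mean-square displacement
#'
#' @param traj data.frame with `t`, `x_um`, `y_um` of one particle, uniformly
#'   sampled.
#' @param max_lag_fraction largest lag as a fraction of the trajectory span
#'   (default 1/4).
#' @return data.frame of class `msd_curve`: `lag_s`, `msd_um2`, `n_pairs`
#'   (the zero lag is included with MSD 0).
#' @export
msd <- function(traj, max_lag_fraction = 0.25) {
  stopifnot(all(c("t", "x_um", "y_um") %in% names(traj)))
  traj <- traj[order(traj$t), ]
  n <- nrow(traj)
  stopifnot(n >= 10)
  dt <- median(diff(traj$t))
  max_lag <- max(1, floor((n - 1) * max_lag_fraction))
  res <- vapply(seq_len(max_lag), function(lag) {
    dx <- traj$x_um[(lag + 1):n] - traj$x_um[1:(n - lag)]
    dy <- traj$y_um[(lag + 1):n] - traj$y_um[1:(n - lag)]
    c(mean(dx^2 + dy^2), n - lag)
  }, numeric(2))
  out <- data.frame(lag_s = c(0, seq_len(max_lag) * dt),
                    msd_um2 = c(0, res[1, ]),
                    n_pairs = c(n, res[2, ]))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Classify a particle as trapped or diffusive and fit D
#'
#' D comes from a pair-count-weighted linear fit `MSD = 4 D tau + offset`
#' over lags 1..10 frames (the offset absorbs static localization error).
#' A particle is trapped when `D < D_trap_threshold` or when the MSD plateau
#' ratio `MSD(10 dt) / MSD(dt)` is below `plateau_ratio_min` (a freely
#' diffusing particle would show a ratio of 10).
#'
#' @param msd_curve result of [msd()], at least 5 nonzero lags.
#' @param dt frame interval (s).
#' @param fit_lags lag indices (in frames) entering the fit.
#' @param D_trap_threshold um^2/s (default 0.01).
#' @param plateau_ratio_min default 3.
#' @return list of class `diffusion_estimate`: `D_um2_s`, `class`,
#'   `offset_um2`, `plateau_ratio`, `fit_lags`.
#' @export
classify_and_fit <- function(msd_curve, dt, fit_lags = 1:10,
                             D_trap_threshold = 0.01,
                             plateau_ratio_min = 3) {
  stopifnot(inherits(msd_curve, "msd_curve") || is.data.frame(msd_curve))
  nz <- msd_curve[msd_curve$lag_s > 0, ]
  if (nrow(nz) < 5) stop("need >= 5 nonzero lags", call. = FALSE)
  fit_lags <- fit_lags[fit_lags <= nrow(nz)]
  sub <- nz[fit_lags, ]
  w <- sub$n_pairs
  fit <- lm(msd_um2 ~ lag_s, data = sub, weights = w)
  D <- unname(coef(fit)[2]) / 4
  if (D < 0) {
    warning("negative fitted D clamped to 0")
    D <- 0
  }
  i10 <- min(10, nrow(nz))
  plateau_ratio <- nz$msd_um2[i10] / nz$msd_um2[1]
  cls <- if (D < D_trap_threshold ||
             (is.finite(plateau_ratio) && plateau_ratio < plateau_ratio_min))
    "trapped" else "diffusive"
  structure(list(D_um2_s = D, class = cls,
                 offset_um2 = unname(coef(fit)[1]),
                 plateau_ratio = plateau_ratio,
                 fit_lags = fit_lags),
            class = "diffusion_estimate")
}

#' Per-particle diffusion analysis of a trajectory table
#'
#' Runs [msd()] and [classify_and_fit()] on every particle and summarizes the
#' diffusive/trapped split.
#'
#' @param traj data.frame with `particle`, `t`, `x_um`, `y_um`.
#' @param dt frame interval (s).
#' @param ... passed to [classify_and_fit()].
#' @return list with `per_particle` (data.frame: `particle`, `D_um2_s`,
#'   `class`, `plateau_ratio`), `trapped_fraction`, `mean_D_diffusive`.
#' @export
analyze_tracks <- function(traj, dt, ...) {
  ids <- unique(traj$particle)
  rows <- lapply(ids, function(p) {
    tr <- traj[traj$particle == p, ]
    if (nrow(tr) < 10) return(NULL)
    est <- classify_and_fit(msd(tr), dt, ...)
    data.frame(particle = p, D_um2_s = est$D_um2_s, class = est$class,
               plateau_ratio = est$plateau_ratio)
  })
  pp <- do.call(rbind, rows)
  list(per_particle = pp,
       trapped_fraction = mean(pp$class == "trapped"),
       mean_D_diffusive = if (any(pp$class == "diffusive"))
         mean(pp$D_um2_s[pp$class == "diffusive"]) else NA_real_)
}

#' Ensemble mean-square displacement
#'
#' Averages the time-averaged MSD of all particles at each lag, weighting by
#' pair counts.
#'
#' @inheritParams analyze_tracks
#' @param max_lag_fraction see [msd()].
#' @return data.frame of class `msd_curve`.
#' @export
ensemble_msd <- function(traj, max_lag_fraction = 0.25) {
  ids <- unique(traj$particle)
  curves <- lapply(ids, function(p) msd(traj[traj$particle == p, ],
                                        max_lag_fraction))
  lags <- sort(unique(unlist(lapply(curves, function(cc) cc$lag_s))))
  agg <- vapply(lags, function(l) {
    vals <- vapply(curves, function(cc) {
      i <- match(l, cc$lag_s)
      if (is.na(i)) c(NA_real_, 0) else c(cc$msd_um2[i], cc$n_pairs[i])
    }, numeric(2))
    w <- vals[2, ]; v <- vals[1, ]
    c(sum(v * w, na.rm = TRUE) / sum(w[!is.na(v)]), sum(w))
  }, numeric(2))
  out <- data.frame(lag_s = lags, msd_um2 = agg[1, ], n_pairs = agg[2, ])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = k_B T / (3 pi eta d)` for a sphere of diameter d, returned in
#' um^2/s. With the defaults (1-um sphere in water at 20 C) this evaluates
#' to 0.43 um^2/s.
#'
#' @param diameter sphere diameter (um).
#' @param temperature kelvin (default 293.15 K).
#' @param viscosity dynamic viscosity (mPa s; water at 20 C is 1.00).
#' @return D in um^2/s.
#' @export
stokes_einstein <- function(diameter = 1, temperature = 293.15,
                            viscosity = 1.00) {
  stopifnot(diameter > 0, temperature > 0, viscosity > 0)
  kb <- 1.380649e-23                       # J/K
  d_m <- diameter * 1e-6
  eta <- viscosity * 1e-3                  # Pa s
  D_m2s <- kb * temperature / (3 * pi * eta * d_m)
  D_m2s * 1e12                             # m^2/s -> um^2/s
}
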