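# Shared fixtures, all built in code.

# pixel-center coordinate grids (um) for an n x n image
grid_um <- function(n, pixel_size) {
  X <- matrix(rep((seq_len(n) - 1) * pixel_size, each = n), n)
  list(X = X, Y = t(X))
}

disk_mask <- function(n, cx, cy, r_px) {
  g <- grid_um(n, 1)
  (g$X - cx)^2 + (g$Y - cy)^2 <= r_px^2
}

ellipse_mask <- function(n, cx, cy, a_px, b_px, pixel_size = 1) {
  g <- grid_um(n, 1)
  ((g$X - cx) / a_px)^2 + ((g$Y - cy) / b_px)^2 <= 1
}

# plus-sign of five unit squares, each `b` pixels on a side
plus_mask <- function(b = 60) {
  m <- matrix(FALSE, 3 * b, 3 * b)
  m[(b + 1):(2 * b), ] <- TRUE
  m[, (b + 1):(2 * b)] <- TRUE
  m
}

quiet_scene <- function(n = 256, pixel_size = 0.2, psf = 0, bg = 0, noise = 0,
                        seed = 1) {
  scene_config(c(n, n), pixel_size, psf_sigma = psf, background_level = bg,
               noise_sd = noise, seed = seed)
}

# non-overlapping spindle field on a grid; returns list(objects, lengths)
spindle_field <- function(n_obj, mean_len, cv, width, seed,
                          cell = c(12.5, 14)) {
  set.seed(seed)
  lens <- rnorm(n_obj, mean_len, cv * mean_len)
  g <- expand.grid(gx = 1:8, gy = 1:7)[seq_len(n_obj), ]
  objs <- lapply(seq_len(n_obj), function(i)
    list(type = "spindle", x = g$gx[i] * cell[1] - 6, y = g$gy[i] * cell[2] - 7,
         length = lens[i], width = width,
         orientation = runif(1, 0, pi), amplitude = 100))
  list(objects = objs, lengths = lens)
}
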