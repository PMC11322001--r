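test_that("beta estimation is exact, noise-robust and contamination-robust", {
  red <- matrix(runif(100 * 100, 50, 150), 100)
  fg <- matrix(TRUE, 100, 100)
  expect_equal(estimate_beta(2 * red, red, fg)$beta, 2)

  set.seed(2)
  green <- 1.4 * red + matrix(rnorm(1e4, 0, 0.05 * mean(1.4 * red)), 100)
  est <- estimate_beta(green, red, fg)
  expect_lt(abs(est$beta - 1.4), 0.05)

  # 10% DNA-positive pixels inflate the mean ratio but not the median
  gb <- 1.4 * red
  contaminated <- sample(1e4, 1e3)
  gb[contaminated] <- gb[contaminated] + 500
  eb <- estimate_beta(gb, red, fg)
  expect_lt(abs(eb$beta / 1.4 - 1), 0.05)
  expect_gt(mean(gb / red), 1.4 * 1.05)

  expect_error(estimate_beta(green[1:5, 1:5], red[1:5, 1:5],
                             matrix(TRUE, 5, 5)), "100")
  negred <- red; negred[1:30, ] <- -1
  expect_error(estimate_beta(green, negred, fg), "non-positive")
})

test_that("unmixing follows the linear identity and stays signed", {
  red <- matrix(runif(64 * 64, 20, 80), 64)
  ds <- matrix(runif(64 * 64, 0, 50), 64)    # dsDNA ground truth
  ss <- matrix(runif(64 * 64, 0, 50), 64)    # ssDNA ground truth
  beta <- 1.4
  green_ff <- beta * red                      # peptide-only bleed-through
  green <- ds + green_ff
  red_tot <- ss + red
  m <- unmix(green, red_tot, beta)
  expect_equal(m, ds - beta * ss + beta * (red - red), tolerance = 1e-10)
  expect_true(any(m < 0))                    # negatives retained

  # peptide-only scene maps to ~0
  expect_lt(max(abs(unmix(green_ff, red, beta))), 1e-10)
  # beta = 0 returns the green channel
  expect_equal(unmix(green, red_tot, 0), green)
  # linearity in a common scale factor
  expect_equal(unmix(3 * green, 3 * red_tot, beta),
               3 * unmix(green, red_tot, beta))
  expect_error(unmix(green[1:10, ], red_tot, beta), "shape")
})

test_that("beta is consistent across image halves on homogeneous scenes", {
  set.seed(4)
  red <- matrix(runif(80 * 80, 40, 120), 80)
  green <- 1.4 * red * matrix(rnorm(6400, 1, 0.05), 80)
  left <- matrix(FALSE, 80, 80); left[, 1:40] <- TRUE
  b1 <- estimate_beta(green, red, left)$beta
  b2 <- estimate_beta(green, red, !left)$beta
  expect_lt(abs(b1 / b2 - 1), 0.05)
})

test_that("cortex series are flat for static shells and recover release decay", {
  cfg <- quiet_scene(192)
  shell_img <- function(amp) render_scene(
    cfg, list(list(type = "shell", x = 19.2, y = 19.2, radius = 15,
                   thickness = 1.5, amplitude = amp)))$image
  cc <- extract_contour(disk_mask(192, 96, 96, 75), 0.2)

  static <- lapply(rep(100, 5), shell_img)
  cs <- cortex_intensity_series(static, cc, times = 0:4, pixel_size = 0.2,
                                band_width = 2)
  expect_lt(sd(cs$intensity) / mean(cs$intensity), 1e-10)

  # bleached, non-releasing series flattens after correction
  bleach <- 0.93
  ser <- lapply(0:5, function(i) shell_img(100) * bleach^i)
  pf <- photobleach_factors(ser)
  corr <- cortex_intensity_series(ser, cc, 0:5, 0.2, bleach_factors = pf,
                                  band_width = 2)
  expect_lt(sd(corr$intensity) / mean(corr$intensity), 1e-6)

  # release + bleach: corrected curve matches the generating exponential
  k <- 0.05
  amp_t <- 20 + 80 * exp(-k * (0:19))
  rel <- lapply(0:19, function(i) shell_img(amp_t[i + 1]) * bleach^i)
  corr2 <- cortex_intensity_series(rel, cc, 0:19, 0.2,
                                   bleach_factors = bleach^(0:19),
                                   band_width = 2)
  scale <- corr2$intensity[1] / amp_t[1]
  expect_lt(max(abs(corr2$intensity / scale - amp_t) / amp_t), 0.02)
})

test_that("release fits recover rates exactly without noise and flag flat curves", {
  t <- 0:19
  exact <- data.frame(t_min = t, intensity = 10 + 90 * exp(-0.05 * t))
  f <- fit_release(exact, n_boot = 30, seed = 1)
  expect_lt(abs(f$k - 0.05), 1e-7)
  expect_lt(max(abs(residuals(f$fit))) / 90, 1e-8)

  flat <- data.frame(t_min = t, intensity = rep(50, 20))
  ff <- fit_release(flat, n_boot = 30, seed = 1)
  expect_lt(ff$k, 1e-6)
  expect_true(ff$flat)
})

test_that("fitted rates preserve the ordering of generating rates across seeds", {
  t <- 0:14
  n_ok <- 0
  for (sd in 1:40) {
    lo <- gen_release_series(kinetics_truth(k = 0.03, I0 = 100, Iinf = 10),
                             frame_times = t, noise_sd = 2, seed = sd)
    hi <- gen_release_series(kinetics_truth(k = 0.10, I0 = 100, Iinf = 10),
                             frame_times = t, noise_sd = 2, seed = sd + 1000)
    klo <- fit_release(data.frame(t_min = t, intensity = lo$release),
                       n_boot = 0)$k
    khi <- fit_release(data.frame(t_min = t, intensity = hi$release),
                       n_boot = 0)$k
    n_ok <- n_ok + (khi > klo)
  }
  expect_gte(n_ok / 40, 0.95)
})

test_that("skipping bleach correction biases the fitted rate upward", {
  ser <- gen_release_series(kinetics_truth(k = 0.05, bleach_factor = 0.97,
                                           I0 = 100, Iinf = 10),
                            n_frames = 20, noise_sd = 0)
  pf <- ser$control / ser$control[1]
  corrected <- fit_release(data.frame(t_min = ser$times,
                                      intensity = ser$release / pf),
                           n_boot = 0)$k
  uncorrected <- fit_release(data.frame(t_min = ser$times,
                                        intensity = ser$release),
                             n_boot = 0)$k
  expect_lt(abs(corrected - 0.05) / 0.05, 0.10)
  expect_gt(uncorrected, corrected)
})
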