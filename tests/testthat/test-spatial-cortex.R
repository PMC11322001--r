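test_that("radial profiles reproduce full, annular and Bernoulli masks", {
  full <- disk_mask(200, 100, 100, 95)
  rp <- radial_probability(full, c(100, 100), 95, 1, n_bins = 10)
  expect_true(all(rp$probability == 1))

  g <- grid_um(200, 1)
  rr <- sqrt((g$X - 100)^2 + (g$Y - 100)^2) / 95
  ann <- rr >= 0.9 & rr <= 1
  rpa <- radial_probability(ann, c(100, 100), 95, 1, n_bins = 10)
  expect_gt(rpa$probability[10], 0.95)
  expect_true(all(rpa$probability[1:9] < 0.05))

  set.seed(5)
  bern <- matrix(runif(200 * 200) < 0.3, 200)
  rpb <- radial_probability(bern, c(100, 100), 95, 1, n_bins = 10)
  # binomial error bound per bin
  err <- 4 / sqrt(rpb$n_pixels * 0.3 * 0.7)
  expect_true(all(abs(rpb$probability - 0.3) < pmax(err, 0.05)))
  expect_error(radial_probability(bern, c(100, 100), 0, 1), "radius")
})

test_that("radial profiles respect union dominance and rotation invariance", {
  set.seed(6)
  m1 <- matrix(runif(160 * 160) < 0.2, 160)
  m2 <- matrix(runif(160 * 160) < 0.2, 160)
  pu <- radial_probability(m1 | m2, c(80, 80), 75, 1)$probability
  p1 <- radial_probability(m1, c(80, 80), 75, 1)$probability
  p2 <- radial_probability(m2, c(80, 80), 75, 1)$probability
  expect_true(all(pu >= p1 - 1e-12 & pu >= p2 - 1e-12))

  # rotation by 90 degrees about the centre leaves the profile unchanged
  g <- grid_um(161, 1)
  blob <- ((g$X - 110)^2 + (g$Y - 80)^2) <= 15^2
  p0 <- radial_probability(blob, c(80, 80), 78, 1)$probability
  rot <- t(blob)[, rev(seq_len(161))]   # 90-degree rotation, square image
  p90 <- radial_probability(rot, c(80, 80), 78, 1)$probability
  expect_equal(p90, p0, tolerance = 0.05)
})

test_that("temporal cross-correlation tracks pattern decay and is symmetric", {
  set.seed(7)
  base <- matrix(runif(100 * 100) < 0.4, 100)
  expect_equal(temporal_cross_correlation(list(base, base, base))$correlation,
               rep(1, 3))
  indep <- lapply(1:4, function(i) matrix(runif(1e4) < 0.4, 100))
  ci <- temporal_cross_correlation(indep)$correlation
  expect_true(all(abs(ci[-1]) < 0.05))

  # translating a disk pattern by growing shifts decays monotonically
  d0 <- disk_mask(100, 30, 50, 12)
  shifts <- lapply(c(0, 4, 8, 16), function(s) disk_mask(100, 30 + s, 50, 12))
  cs <- temporal_cross_correlation(shifts)$correlation
  expect_equal(cs[1], 1)
  expect_true(all(diff(cs) < 0))

  expect_warning(
    cc <- temporal_cross_correlation(list(base, matrix(TRUE, 100, 100))),
    "constant")
  expect_true(is.na(cc$correlation[2]))
})

test_that("contour correlation matches closed forms", {
  # cosine trace: C(lag) = cos(2 pi lag / P), xi_c = (P/2pi) acos(1/e)
  P <- 10; spacing <- 0.5; n <- 200
  sig <- cos(2 * pi * (0:(n - 1)) * spacing / P)
  cc <- contour_correlation(sig, spacing)
  expect_equal(cc$C[1], 1)
  expect_equal(cc$C, cos(2 * pi * cc$lag_um / P), tolerance = 1e-9)
  expect_lt(abs(cc$xi_c_um - P / (2 * pi) * acos(exp(-1))), 0.02)

  set.seed(8)
  wn <- rnorm(400)
  cw <- contour_correlation(wn, 0.5)
  expect_lte(cw$xi_c_um, 2 * 0.5)

  # wider boxcar blobs carry longer correlation lengths
  xi_of_width <- function(w) {
    s <- rep(0, 200); s[1:w] <- 1
    contour_correlation(s, 1)$xi_c_um
  }
  xis <- vapply(c(10, 20, 40), xi_of_width, numeric(1))
  expect_true(all(diff(xis) > 0))
  expect_error(contour_correlation(rep(1, 100), 1), "zero-variance")
  expect_error(contour_correlation(rnorm(10), 1), "50")
})

test_that("shell-band traces see gaps and recover cortical cluster size", {
  # uniform shell -> constant trace
  cfg <- quiet_scene(256)
  sc <- render_scene(cfg, list(list(type = "shell", x = 25.6, y = 25.6,
                                    radius = 20, thickness = 2,
                                    amplitude = 100)))
  dmask <- disk_mask(256, 128, 128, 100)
  cc <- extract_contour(dmask, 0.2)
  tr <- shell_band_signal(sc$image, cc, band_width = 2, pixel_size = 0.2)
  expect_lt(sd(tr$signal) / mean(tr$signal), 0.05)

  # a gap in the shell dips at the gap angle
  img2 <- sc$image
  g <- grid_um(256, 0.2)
  ang <- atan2(g$Y - 25.6, g$X - 25.6)
  img2[abs(ang) < 0.3] <- 0
  tr2 <- shell_band_signal(img2, cc, 2, 0.2)
  gap_s <- tr2$signal[abs(atan2(cc$y - 25.6, cc$x - 25.6)) < 0.2]
  rest <- tr2$signal[abs(atan2(cc$y - 25.6, cc$x - 25.6)) > 0.5]
  expect_lt(mean(gap_s), 0.2 * mean(rest))
  expect_error(shell_band_signal(sc$image, cc, band_width = 50, 0.2), "band")

  # clustered shell: xi_c ~ cluster arc size
  set.seed(9)
  cluster_halfwidth <- 2      # um of arc
  R <- 20
  ang_c <- runif(6, -pi, pi)
  img3 <- matrix(0, 256, 256)
  rr <- sqrt((g$X - 25.6)^2 + (g$Y - 25.6)^2)
  for (a in ang_c) {
    dang <- abs(((ang - a + pi) %% (2 * pi)) - pi)
    img3[rr >= R - 2 & rr <= R & dang < cluster_halfwidth / R] <- 100
  }
  tr3 <- shell_band_signal(img3, cc, 2, 0.2)
  cc3 <- contour_correlation(tr3$signal, tr3$spacing_um)
  # boxcar autocorrelation oracle: a cluster of full arc width w has a
  # triangular C(lag) crossing 1/e at (1 - 1/e) w
  w_full <- 2 * cluster_halfwidth
  xi_pred <- (1 - exp(-1)) * w_full
  expect_lt(abs(cc3$xi_c_um - xi_pred) / xi_pred, 0.3)
})
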