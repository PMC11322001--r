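test_that("tangent angles match straight-line and circular-arc geometry", {
  x <- seq(0, 5, length.out = 50)
  expect_true(all(tangent_angles(backbone(x, rep(0, 50)))$theta == 0))
  th45 <- tangent_angles(backbone(x, x))$theta
  expect_true(all(abs(th45 - pi / 4) < 1e-12))
  # quarter circle: theta linear in s, total change pi/2
  phi <- seq(0, pi / 2, length.out = 200)
  arc <- backbone(10 * cos(phi), 10 * sin(phi))
  ta <- tangent_angles(arc)
  expect_equal(diff(range(ta$theta)), pi / 2, tolerance = 0.01)
  expect_gt(abs(cor(ta$s, ta$theta)), 0.9999)
  expect_error(backbone(c(1, 1, 1:8), c(2, 2, 1:8)), "duplicate")
})

test_that("mode projection recovers a single injected mode", {
  L <- 6
  s <- seq(0, L, length.out = 400)
  for (k1 in 1:3) {
    c0 <- 0.05
    u <- c0 * eigenfunctions(k1, L, s)$y
    sm <- (s[-1] + s[-length(s)]) / 2
    th <- atan2(diff(u), diff(s))
    sp <- mode_amplitudes(th, sm, L, k_max = 4)
    expect_lt(abs(sp$a[k1] / c0 - 1), 0.02)
    expect_true(all(abs(sp$a[-k1]) < 0.02 * c0))
  }
  # straight filament: all amplitudes vanish
  sp0 <- mode_amplitudes(rep(0, 100), seq(0.01, 5.99, length.out = 100), 6, 4)
  expect_true(all(sp0$a == 0))
  # rigid rotation leaves the projection unchanged
  u <- 0.05 * eigenfunctions(2, L, s)$y
  sm <- (s[-1] + s[-length(s)]) / 2
  th <- atan2(diff(u), diff(s))
  a0 <- mode_amplitudes(th, sm, L, 4)$a
  a1 <- mode_amplitudes(th + 0.3, sm, L, 4)$a
  expect_lt(max(abs(a1 - a0)), 1e-3)
  expect_error(mode_amplitudes(th, sm, L, k_max = 11), "resolution")
})

test_that("round trip through tangent angles recovers sampled amplitudes", {
  tr <- gen_fluctuating_filament(
    filament_truth(L = 6, kappa = 0.2, frames = 30), seed = 21)
  sp <- backbone_spectra(tr$backbones, k_max = 4)
  for (k in 1:4) {
    slope <- coef(lm(sp$amplitudes[, k] ~ tr$amplitudes[, k]))[2]
    expect_lt(abs(slope - 1), 0.02)
  }
})

test_that("stiffness is recovered within 10% and temperature cancels", {
  tr <- gen_fluctuating_filament(
    filament_truth(L = 6, kappa = 0.04, temperature = 293, frames = 500),
    seed = 7)
  sp <- suppressWarnings(backbone_spectra(tr$backbones, k_max = 4))
  est <- estimate_kappa(sp, temperature = 293)
  expect_lt(abs(est$kappa / 0.04 - 1), 0.10)
  expect_equal(est$persistence_length, est$kappa / kBT(293))
  expect_lt(abs(est$free_exponent - (-4)), 0.5)

  tr2 <- gen_fluctuating_filament(
    filament_truth(L = 6, kappa = 0.04, temperature = 586, frames = 500),
    seed = 7)
  sp2 <- suppressWarnings(backbone_spectra(tr2$backbones, k_max = 4))
  est2 <- estimate_kappa(sp2, temperature = 586)
  expect_lt(abs(est2$kappa / est$kappa - 1), 0.15)

  dup <- sp
  dup$amplitudes <- sp$amplitudes[rep(1, 120), ]
  expect_error(estimate_kappa(dup), "variance")
  expect_error(estimate_kappa(sp, fit_modes = 2), "2 modes")
})

test_that("kappa recovery is unbiased over seeds and rigid-motion invariant", {
  kappas <- vapply(1:12, function(sd) {
    tr <- gen_fluctuating_filament(
      filament_truth(L = 6, kappa = 0.04, frames = 250), seed = sd)
    sp <- suppressWarnings(backbone_spectra(tr$backbones, k_max = 4))
    estimate_kappa(sp)$kappa
  }, numeric(1))
  se <- sd(kappas) / sqrt(length(kappas))
  expect_lt(abs(mean(kappas) - 0.04), 3 * se)

  # rigid rotation + translation of every backbone leaves kappa unchanged
  tr <- gen_fluctuating_filament(
    filament_truth(L = 6, kappa = 0.04, frames = 200), seed = 31)
  rot <- 0.7; R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  moved <- lapply(tr$backbones, function(b) {
    p <- R %*% rbind(b$x, b$y)
    backbone(p[1, ] + 3, p[2, ] - 2, b$frame)
  })
  k0 <- estimate_kappa(suppressWarnings(backbone_spectra(tr$backbones, 4)))$kappa
  k1 <- estimate_kappa(suppressWarnings(backbone_spectra(moved, 4)))$kappa
  expect_equal(k1, k0, tolerance = 1e-6)
})

test_that("backbones are traced from masks to within a few percent in length", {
  rigid <- gen_fluctuating_filament(
    filament_truth(L = 6, kappa = 1e6, frames = 1), seed = 1)
  b <- rigid$backbones[[1]]
  cfg <- scene_config(c(200, 200), 0.1, psf_sigma = 0.15,
                      background_level = 0, noise_sd = 0)
  sc <- render_scene(cfg, list(list(type = "filament", x_coords = b$x + 5,
                                    y_coords = b$y + 10, amplitude = 50)))
  # half-max boundary sits on the true edge of a blurred ridge end
  mk <- binarize(sc$image, "fixed", threshold = 0.5 * max(sc$image))
  tb <- trace_backbone(mk, 0.1)
  expect_lt(abs(tb$L / 6 - 1), 0.03)

  # horizontal 1-px line of 50 pixels at 0.2 um/px: L = 9.8 um +- 1 px
  line <- matrix(FALSE, 20, 60)
  line[10, 6:55] <- TRUE
  tl <- trace_backbone(line, 0.2)
  expect_lt(abs(tl$L - 9.8), 0.21)

  # T-branch is rejected with branch points listed
  tee <- matrix(FALSE, 21, 21)
  tee[11, 3:19] <- TRUE
  tee[3:11, 11] <- TRUE
  expect_error(trace_backbone(tee, 0.2), "branch")
  two <- matrix(FALSE, 20, 20)
  two[5, 2:18] <- TRUE; two[15, 2:18] <- TRUE
  expect_error(trace_backbone(two, 0.2), "components")
})

test_that("backbone CSV round trip preserves coordinates", {
  tr <- gen_fluctuating_filament(filament_truth(frames = 3), seed = 2)
  path <- file.path(tempdir(), "bb.csv")
  write_backbones(tr$backbones, path)
  back <- read_backbones(path)
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$x, tr$backbones[[2]]$x, tolerance = 1e-12)
})
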