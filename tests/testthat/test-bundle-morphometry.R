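test_that("rectangles and disks are measured with the expected dimensions", {
  cfg <- quiet_scene(256)
  sc <- render_scene(cfg, list(list(type = "rect", x = 25, y = 25, length = 10,
                                    width = 1, orientation = 0.4,
                                    amplitude = 100)))
  rec <- segment_bundles(binarize(sc$image, "fixed", threshold = 50), 0.2)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$length_um - 10), 0.3)
  expect_lt(abs(rec$width_um - 1), 0.2)
  expect_lt(abs(rec$aspect_ratio - 10), 1)
  expect_lt(abs(rec$orientation_rad - 0.4), 0.05)

  scd <- render_scene(cfg, list(list(type = "disk", x = 25, y = 25, radius = 4,
                                     amplitude = 100)))
  dd <- segment_bundles(binarize(scd$image, "fixed", threshold = 50), 0.2)
  expect_lte(dd$aspect_ratio, 1.3)
  expect_gte(dd$aspect_ratio, 1)
})

test_that("a synthetic tactoid field is fully recovered object by object", {
  sf <- spindle_field(50, mean_len = 5.4, cv = 0.15, width = 1.2, seed = 99)
  cfg <- scene_config(c(512, 512), 0.2, psf_sigma = 0.2,
                      background_level = 10, noise_sd = 2, seed = 5)
  sc <- render_scene(cfg, sf$objects)
  mk <- binarize(sc$image, "fixed",
                 threshold = cfg$background_level + 3 * cfg$noise_sd)
  rec <- segment_bundles(mk, 0.2, min_area = 1, image = sc$image)
  expect_equal(nrow(rec), 50)
  # match each record to the nearest truth object
  tx <- sc$truth$x_um; ty <- sc$truth$y_um
  match_idx <- vapply(seq_len(nrow(rec)), function(i)
    which.min((tx - rec$centroid_x_um[i])^2 + (ty - rec$centroid_y_um[i])^2),
    integer(1))
  expect_equal(sort(match_idx), 1:50)  # one-to-one
  rel <- rec$length_um / sc$truth$length_um[match_idx] - 1
  expect_true(all(abs(rel) < 0.10))
})

test_that("lengths and widths scale linearly with pixel size", {
  mask <- matrix(FALSE, 64, 64)
  mask[30:34, 10:54] <- TRUE
  a <- segment_bundles(mask, 0.2)
  b <- segment_bundles(mask, 0.4)
  expect_equal(b$length_um, 2 * a$length_um)
  expect_equal(b$width_um, 2 * a$width_um)
  expect_equal(b$aspect_ratio, a$aspect_ratio)
})

test_that("thin/large classification uses a strict threshold", {
  recs <- data.frame(label = 1:3, width_um = c(0.5, 1.0, 1.5))
  out <- classify_bundles(recs, width_threshold = 1.0)
  expect_equal(out$size_class, c("thin", "large", "large"))
  sf <- data.frame(label = 1:100,
                   width_um = c(runif(40, 0.3, 0.9), runif(60, 1.1, 3)))
  cl <- classify_bundles(sf)
  expect_equal(sum(cl$size_class == "thin"), 40)
})

test_that("line scans detect ridge peaks with the Gaussian FWHM", {
  cfg <- scene_config(c(128, 128), 0.2, psf_sigma = 0.42,
                      background_level = 0, noise_sd = 0)
  objs <- lapply(c(8, 12.8, 17.6), function(x0)
    list(type = "rect", x = x0, y = 12.8, length = 20, width = 0.2,
         orientation = pi / 2, amplitude = 100))
  sc <- render_scene(cfg, objs)
  ls3 <- line_scan(sc$image, c(2, 12.8), c(23, 12.8), 0.2)
  expect_equal(nrow(ls3$peaks), 3)
  # a thin ridge blurred by sigma = 0.42 um has FWHM 2.355 * 0.42 ~ 1 um
  expect_true(all(abs(ls3$peaks$fwhm_um - 1) < 0.15))
  flat <- line_scan(matrix(5, 32, 32), c(0.5, 1), c(5, 1), 0.2)
  expect_equal(nrow(flat$peaks), 0)
  expect_error(line_scan(sc$image, c(1, 1), c(1, 1), 0.2), "coincide")
})

test_that("power-law fits are exact on exact data and match a grid search", {
  x <- c(0.1, 0.5, 1, 2)
  y <- 5 * x^(-0.33)
  f <- fit_power_law(x, y)
  expect_equal(f$exponent, -0.33, tolerance = 1e-12)
  expect_equal(f$prefactor, 5, tolerance = 1e-10)
  fc <- fit_power_law(x, rep(3, 4))
  expect_equal(fc$exponent, 0, tolerance = 1e-12)
  expect_error(fit_power_law(c(-1, 1, 2), c(1, 1, 1)))
  expect_error(fit_power_law(c(1, 1, 1), c(1, 2, 3)))

  # brute-force grid minimization of squared log residuals agrees
  set.seed(1)
  xs <- rep(c(0.1, 0.5, 1, 2), each = 5)
  ys <- 4 * xs^(-0.4) * exp(rnorm(20, 0, 0.1))
  ff <- fit_power_law(xs, ys)
  grid_loss <- function(b) {
    a <- mean(log(ys) - b * log(xs))
    sum((log(ys) - a - b * log(xs))^2)
  }
  bs <- seq(-1, 0, by = 1e-4)
  best <- bs[which.min(vapply(bs, grid_loss, numeric(1)))]
  expect_lt(abs(ff$exponent - best), 1e-4 + 1e-6)
})

test_that("lognormal populations generated at exponent -0.33 are recovered", {
  set.seed(123)
  fractions <- c(0.1, 0.5, 1, 2)
  x <- rep(fractions, each = 100)
  y <- 8 * x^(-0.33) * exp(rnorm(length(x), 0, 0.2))
  f <- fit_power_law(x, y)
  expect_lt(abs(f$exponent - (-0.33)), 0.05)
})

test_that("alignment fraction separates oriented from isotropic textures", {
  cfg <- scene_config(c(128, 128), 0.2, psf_sigma = 0.3,
                      background_level = 0, noise_sd = 0)
  objs <- lapply(seq(4, 22, by = 2), function(y0)
    list(type = "rect", x = 12.8, y = y0, length = 24, width = 0.3,
         orientation = 0, amplitude = 100))
  sc <- render_scene(cfg, objs)
  expect_gt(orientation_coherence(sc$image, 0.2, tensor_sigma = 1), 0.9)
  for (sd in 1:3) {
    set.seed(sd)
    noise <- matrix(runif(128 * 128, 50, 150), 128)
    expect_lt(orientation_coherence(noise, 0.2, tensor_sigma = 1), 0.2)
  }
  expect_error(orientation_coherence(matrix(1, 16, 16), 0.2), "constant")
})

test_that("alignment fraction is close to rotation invariant", {
  cfg <- scene_config(c(160, 160), 0.2, psf_sigma = 0.3,
                      background_level = 0, noise_sd = 0)
  mk_ridges <- function(ori) {
    ctr <- 16
    objs <- lapply(seq(-8, 8, by = 2), function(off)
      list(type = "rect", x = ctr + off * sin(ori), y = ctr - off * cos(ori),
           length = 20, width = 0.3, orientation = ori, amplitude = 100))
    render_scene(cfg, objs)$image
  }
  c0 <- orientation_coherence(mk_ridges(0), 0.2, 1)
  c37 <- orientation_coherence(mk_ridges(37 * pi / 180), 0.2, 1)
  expect_lt(abs(c37 - c0) / c0, 0.02)
})
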