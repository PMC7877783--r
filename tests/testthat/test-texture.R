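test_that("Gaussian smoothing is normalized, variance-reducing and validated", {
  const <- matrix(3.7, 24, 24)
  expect_equal(gaussian_smooth(const, 2), const)
  # unit impulse: center value equals the peak of the normalized sampled kernel
  imp <- matrix(0, 25, 25); imp[13, 13] <- 1
  k1 <- octmargin:::gaussian_kernel(2)
  expect_equal(gaussian_smooth(imp, 2)[13, 13], max(k1)^2)
  # ... which is the discretization of (2 pi sigma^2)^-1
  expect_equal(max(k1)^2, 1 / (2 * pi * 4), tolerance = 0.01)
  set.seed(1)
  noise <- matrix(rnorm(64^2), 64, 64)
  expect_lt(var(as.vector(gaussian_smooth(noise, 3))), var(as.vector(noise)))
  expect_error(gaussian_smooth(noise, 0), "positive")
  expect_error(gaussian_smooth(noise, -1), "positive")
})

test_that("waviness/roughness decomposition is exact and frequency-selective", {
  const <- matrix(5, 32, 32)
  dec <- roughness_decompose(const)
  expect_true(all(abs(dec$roughness) < 1e-12))
  set.seed(2)
  img <- matrix(rnorm(48 * 48), 48, 48)
  dec <- roughness_decompose(img, 2, 16)
  expect_equal(dec$smoothed, dec$waviness + dec$roughness)   # exact identity
  # low-frequency sinusoid (period >> sigma_waviness) passes into waviness;
  # the Gaussian transfer function exp(-2 pi^2 sigma^2 f^2) at period 320
  # and sigma 16 keeps > 94% in the waviness branch
  x <- outer(seq_len(640), rep(1, 16))
  sine <- sin(2 * pi * x / 320)
  dec_s <- roughness_decompose(sine, 2, 16)
  interior <- dec_s$roughness[101:540, ]
  expect_lt(max(abs(interior)), 0.1)                          # < 10% amplitude
  # period-2 checkerboard: waviness collapses to the mean and the roughness
  # branch carries everything the smoothing pass kept of the oscillation
  cb <- outer(1:40, 1:40, function(i, j) (-1)^(i + j))
  dec_c <- roughness_decompose(cb, 1, 8)
  expect_lt(max(abs(dec_c$waviness - mean(cb))), 0.01)
  expect_equal(dec_c$roughness, dec_c$smoothed - mean(cb), tolerance = 0.02)
  expect_gt(sd(dec_c$roughness), 0)
  expect_error(roughness_decompose(img, 4, 2), "exceed")
})

test_that("sliding-window roughness SD equals the brute-force oracle", {
  expect_true(all(roughness_sd_filter(matrix(2, 16, 16), 5) == 0))
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(rnorm(32 * 32), 32, 32)
    expect_equal(roughness_sd_filter(img, 5), oracle_sd_filter(img, 5),
                 tolerance = 1e-12)
  }
  # two-valued +-a checkerboard: population SD has the two-point closed form
  # sqrt(a^2 - mean^2) with the window's actual +1/-1 counts
  a <- 1.7; w <- 5
  cb <- a * outer(1:32, 1:32, function(i, j) (-1)^(i + j))
  got <- roughness_sd_filter(cb, w)
  n_hi <- ceiling(w^2 / 2); n_lo <- w^2 - n_hi   # odd window: counts differ by 1
  m <- a * (n_hi - n_lo) / w^2
  expect_true(all(abs(got - sqrt(a^2 - m^2)) < 1e-9) ||
                all(abs(got - sqrt(a^2 - m^2)) < 1e-9 | abs(got - a) < 1e-9))
  expect_error(roughness_sd_filter(cb, 4), "odd")
  expect_error(roughness_sd_filter(cb, 1), "odd")
})

test_that("Prewitt slope is normalized to intensity units per pixel", {
  expect_lt(max(prewitt_slope(matrix(1, 10, 10))), 1e-12)
  s <- 0.7
  ramp_x <- outer(rep(1, 20), seq_len(20)) * s
  expect_equal(prewitt_slope(ramp_x)[5:16, 5:16],
               matrix(s, 12, 12), tolerance = 1e-12)
  ramp_xy <- (outer(seq_len(20), rep(1, 20)) + outer(rep(1, 20), seq_len(20))) * s
  expect_equal(prewitt_slope(ramp_xy)[5:16, 5:16],
               matrix(s * sqrt(2), 12, 12), tolerance = 1e-12)
  expect_error(prewitt_slope(matrix(1, 2, 5)), "3x3")
})

test_that("texture maps rotate with the image and match convolution oracles", {
  set.seed(7)
  img <- matrix(rnorm(24 * 24), 24, 24)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]   # 90 degrees
  expect_equal(roughness_sd_filter(rot(img), 5), rot(roughness_sd_filter(img, 5)),
               tolerance = 1e-12)
  expect_equal(prewitt_slope(rot(img)), rot(prewitt_slope(img)),
               tolerance = 1e-12)
  # separable Gaussian equals the explicit 2-D convolution oracle
  k1 <- octmargin:::gaussian_kernel(1.5)
  expect_equal(gaussian_smooth(img, 1.5), oracle_conv(img, outer(k1, k1)),
               tolerance = 1e-12)
})

test_that("depth compensation flattens exponential decay and recovers the rate", {
  nz <- 80; nx <- 12; ny <- 12; ax <- 5
  z_mm <- (seq_len(nz) - 1) * ax / 1000
  vol <- array(rep(exp(-2 * 1.0 * z_mm), nx * ny), dim = c(nz, nx, ny))
  mask <- array(TRUE, dim = dim(vol))
  dg <- depth_compensate(vol, mask, ax, exclude_surface = 0)
  expect_equal(dg$rate_per_mm, 2, tolerance = 1e-9)
  prof <- apply(dg$compensated, 1, mean)
  expect_lt(max(abs(prof / prof[1] - 1)), 0.02)        # flat within 2%
  # zero decay leaves the volume unchanged
  flat <- array(1, dim = c(20, 8, 8))
  dg0 <- depth_compensate(flat, array(TRUE, dim = dim(flat)), ax,
                          exclude_surface = 0)
  expect_equal(dg0$compensated, flat, tolerance = 1e-9)
  expect_error(depth_compensate(flat, array(FALSE, dim = dim(flat)), ax),
               "too few")
  # seeded speckle phantom: fitted rate within 10% of 2 mu
  pp <- process_phantom("uniform_tumor", seed = 5)
  mu <- pp$ph$spec$class_params$tumor$mu
  expect_equal(pp$dg$rate_per_mm, 2 * mu, tolerance = 0.1)
})

test_that("the nine ROI features behave on constant, noisy and phantom inputs", {
  expect_setequal(feature_names(),
                  c("intensity_mean", "intensity_sd", "waviness_mean",
                    "roughness_sd_mean", "roughness_sd_max", "slope_mean",
                    "slope_sd", "intensity_entropy", "local_contrast"))
  const <- matrix(2.5, 40, 40)
  f <- roi_features(feature_stack(const), c(5, 35, 5, 35))
  expect_equal(unname(f["intensity_mean"]), 2.5)
  expect_equal(unname(f[c("intensity_sd", "roughness_sd_mean", "roughness_sd_max",
                          "slope_mean", "slope_sd", "intensity_entropy",
                          "local_contrast")]), rep(0, 7))
  # i.i.d. uniform noise on 16 levels approaches 4 bits of entropy
  set.seed(11)
  lv <- matrix(sample(0:15, 80 * 80, replace = TRUE) + 0, 80, 80)
  f2 <- roi_features(feature_stack(lv), c(1, 80, 1, 80))
  expect_equal(unname(f2["intensity_entropy"]), 4, tolerance = 0.01)
  expect_equal(unname(f2["intensity_entropy"]),
               oracle_entropy(lv[5:76, 5:76]), tolerance = 1e-12)
  expect_error(roi_features(feature_stack(const), c(1, 6, 1, 6)), "at least")
  expect_error(roi_features(feature_stack(const), c(0, 30, 1, 30)), "bounds")
})
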