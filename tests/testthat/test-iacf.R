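test_that("threshold zeroing follows the elementwise rule", {
  set.seed(61)
  img <- matrix(runif(100), 10, 10)
  expect_equal(threshold_image(img, 0), img)
  expect_equal(threshold_image(img, max(img) * 1.01), matrix(0, 10, 10))
  thr <- median(img)
  out <- threshold_image(img, thr)
  expect_true(all(out[img < thr] == 0))
  expect_true(all(out[img >= thr] == img[img >= thr]))
})

test_that("normalized autocorrelation matches closed forms on degenerate images", {
  # single nonzero pixel: delta autocorrelation, all zero after center cut
  img <- matrix(0, 16, 16); img[5, 7] <- 3
  M <- normalized_autocorrelation(img)
  expect_equal(max(abs(M)), 0)
  # two equal pixels at lag d: 0.5 at +-d, zero elsewhere
  img2 <- matrix(0, 16, 16); img2[4, 6] <- 2; img2[9, 10] <- 2
  M2 <- normalized_autocorrelation(img2)
  cx <- 16; cy <- 16  # zero-lag position
  expect_equal(M2[cx + 5, cy + 4], 0.5, tolerance = 1e-12)
  expect_equal(M2[cx - 5, cy - 4], 0.5, tolerance = 1e-12)
  M2[cx + 5, cy + 4] <- 0; M2[cx - 5, cy - 4] <- 0
  expect_lt(max(abs(M2)), 1e-12)
  # symmetry under lag negation
  img3 <- matrix(runif(64), 8, 8)
  M3 <- normalized_autocorrelation(img3)
  expect_equal(M3, M3[rev(seq_len(nrow(M3))), rev(seq_len(ncol(M3)))],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(normalized_autocorrelation(matrix(0, 8, 8)), "all-zero")
})

test_that("correlation width scales with Gaussian blob size (sigma sqrt(2) law)", {
  blob <- function(sigma, n = 128) {
    d <- seq_len(n) - (n + 1) / 2
    exp(-outer(d^2, d^2, `+`) / (2 * sigma^2))
  }
  width_of <- function(sigma) {
    M <- normalized_autocorrelation(blob(sigma))
    cs <- M[, (ncol(M) + 1L) %/% 2L]
    cs[(length(cs) + 1L) %/% 2L] <- 1   # restore eliminated center
    measure_fwhm(cs)
  }
  w4 <- width_of(4); w8 <- width_of(8)
  expect_equal(w8 / w4, 2, tolerance = 0.05)
  # absolute check: autocorrelation of a Gaussian of width sigma has
  # width sigma*sqrt(2), i.e. FWHM = 2.3548 * sigma * sqrt(2)
  expect_equal(w4, 2 * sqrt(2 * log(2)) * 4 * sqrt(2), tolerance = 0.05)
})

test_that("FFT autocorrelation equals the brute-force pairwise oracle", {
  set.seed(62)
  img <- matrix(rexp(64 * 64), 64, 64)
  img[img < 1] <- 0
  M <- normalized_autocorrelation(img)
  c0 <- sum(img^2)
  for (lag in list(c(0, 1), c(3, 0), c(5, 7), c(-4, 2), c(11, -13))) {
    dx <- lag[1]; dy <- lag[2]
    xs <- max(1, 1 - dx):min(64, 64 - dx)
    ys <- max(1, 1 - dy):min(64, 64 - dy)
    brute <- sum(img[xs, ys] * img[xs + dx, ys + dy]) / c0
    expect_equal(M[64 + dx, 64 + dy], brute, tolerance = 1e-10)
  }
})

test_that("IACF integrates the central window and is scale invariant", {
  img2 <- matrix(0, 32, 32); img2[10, 10] <- 2; img2[13, 14] <- 2
  M2 <- normalized_autocorrelation(img2)
  expect_equal(iacf(M2, 10), 1.0, tolerance = 1e-12)
  expect_equal(iacf(matrix(0, 61, 61), 30), 0)
  expect_error(iacf(M2, 40), "window")
  # scale invariance of the full image statistic
  set.seed(63)
  img <- matrix(rexp(96 * 96), 96, 96)
  cfg1 <- iacf_config(threshold = 1, roi_diameter_mm = 0.9,
                      pixel_pitch_um = 11, integration_halfwidth = 20)
  cfg5 <- cfg1; cfg5$threshold <- 5
  r1 <- iacf_of_image(img, cfg1)
  r5 <- iacf_of_image(5 * img, cfg5)
  expect_equal(r5$iacf, r1$iacf, tolerance = 1e-10)
})

test_that("spatial smoothing raises the IACF at constant variance", {
  cfg <- iacf_config(threshold = 0.5, roi_diameter_mm = 0.9,
                     pixel_pitch_um = 11, integration_halfwidth = 20)
  d_noise <- numeric(20); d_smooth <- numeric(20)
  for (s in 1:20) {
    set.seed(200 + s)
    noise <- matrix(rnorm(96 * 96), 96, 96)
    smooth <- psoct:::gaussian_random_field(96, 96, 4)
    d_noise[s] <- iacf_of_image(noise^2, cfg)$iacf
    d_smooth[s] <- iacf_of_image(smooth^2, cfg)$iacf
  }
  expect_gt(mean(d_smooth), mean(d_noise))
})

test_that("IACF rises monotonically when texture correlation length grows with depth", {
  v <- texture_volume(nx = 384, ny = 384, n_planes = 16,
                      amplitude_fun = function(u) 0.03,
                      length_fun = function(u) 15 + (120 - 15) * u,
                      sparsity_fun = function(u) 0.85, seed = 5)
  cfg <- iacf_config(roi_diameter_mm = 4.2, pixel_pitch_um = 11)
  p <- iacf_depth_profile(v, cfg, depths = 0:15, noise_depth = 18)
  expect_gt(cor(0:15, p$profile$iacf, method = "spearman"), 0.9)
})

test_that("falling texture amplitude lowers intensity without a width-driven IACF rise", {
  v <- texture_volume(nx = 256, ny = 256, n_planes = 12,
                      amplitude_fun = function(u) 0.03 * exp(-1.2 * u),
                      length_fun = function(u) 30,
                      sparsity_fun = function(u) 0.85, seed = 6)
  cfg <- iacf_config(roi_diameter_mm = 2.8, pixel_pitch_um = 11)
  p <- iacf_depth_profile(v, cfg, depths = 0:11, noise_depth = 14)
  expect_lt(cor(0:11, p$profile$integrated_intensity, method = "spearman"),
            -0.9)
  expect_lt(cor(0:11, p$profile$iacf, method = "spearman"), 0.6)
})

test_that("signal-free planes sit at the noise floor of the statistic", {
  v <- texture_volume(nx = 256, ny = 256, n_planes = 8, n_noise_planes = 3,
                      seed = 7)
  cfg <- iacf_config(roi_diameter_mm = 2.8, pixel_pitch_um = 11)
  p <- iacf_depth_profile(v, cfg, depths = c(0:7, 9, 10), noise_depth = 8)
  stromal <- p$profile$iacf[1:8]
  noisefloor <- p$profile$iacf[9:10]
  expect_lt(max(noisefloor), 0.2 * mean(stromal))
  expect_lt(max(p$profile$n_above_threshold[9:10]),
            0.05 * sum(circular_roi_mask(256, 256, 2800 / 11)))
})
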