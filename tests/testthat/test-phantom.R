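test_that("single-mirror fringe reconstructs at the right depth with the right width", {
  sp <- wide_spectrometer()
  cal <- calibration_from_models(list(co = sp))
  for (z in c(250, 500, 800)) {
    s <- mirror_spectrum(z, 0, sp, cal, channel = "co")
    a <- ascan_from_spectrum(s)
    L <- attr(a, "fft_length")
    zax <- depth_axis_um(length(a), cal$dk, L)
    ipk <- which.max(a[20:length(a)]) + 19L
    expect_lt(abs(zax[ipk] - z), pi / (L * cal$dk) * (L / length(cal$k_grid)))
    # transform-limited width of the Gaussian source (magnitude A-scan)
    expect_lt(abs(psf_fwhm_um(s, cal) -
                    transform_limited_resolution_um(default_source)),
              0.05 * transform_limited_resolution_um(default_source))
  }
})

test_that("quadratic sample dispersion broadens the PSF as the dense-FFT oracle predicts", {
  sp <- spectrometer_model(1024, "co")
  cal <- calibration_from_models(list(co = sp))
  k <- cal$k_grid
  # oracle: dense FFT of the envelope with the same quadratic phase,
  # independent of the fringe-simulation/resampling path
  oracle_fwhm <- function(a2) {
    env <- source_envelope(default_source, k)
    z0 <- pi / (4 * cal$dk)
    s <- env * exp(1i * (2 * k * z0 + a2 * (k - default_source$k0)^2))
    L <- 16L * length(k)
    y <- Mod(stats::fft(c(s, complex(L - length(k)))))[1:(L / 2)]
    measure_fwhm(y, pi * (0:(L / 2 - 1)) / (L * cal$dk))
  }
  f0 <- psf_fwhm_um(mirror_spectrum(400, 0, sp, cal, channel = "co"), cal)
  for (a2 in c(6, 12)) {
    f <- psf_fwhm_um(mirror_spectrum(400, a2, sp, cal, channel = "co"), cal)
    expect_gt(f, f0)
    expect_lt(abs(f - oracle_fwhm(a2)) / oracle_fwhm(a2), 0.05)
  }
  expect_lt(abs(f0 - oracle_fwhm(0)) / oracle_fwhm(0), 0.05)
})

test_that("reflector depths beyond the unambiguous range are rejected with a range report", {
  sp <- spectrometer_model(512, "co")
  zmax <- nyquist_depth_um(sp)
  expect_error(
    simulate_fringe(data.frame(depth_um = zmax * 1.1, amplitude = 1),
                    default_source, sp),
    "unambiguous range")
  expect_silent(
    simulate_fringe(data.frame(depth_um = zmax * 0.9, amplitude = 1),
                    default_source, sp))
})

test_that("the compensation phase term conserves A-scan energy (Parseval)", {
  sp <- spectrometer_model(512, "co")
  cal <- calibration_from_models(list(co = sp))
  s <- mirror_spectrum(300, 0, sp, cal, channel = "co")
  e0 <- sum(Mod(analytic_signal(s))^2)
  for (a2 in c(-8, 3, 20)) {
    sc <- analytic_signal(s) * exp(1i * a2 * (cal$k_grid - cal$k0)^2)
    expect_equal(sum(Mod(sc)^2), e0, tolerance = 1e-12)
  }
})

test_that("volumes are bit-identical for equal seeds and differ across seeds", {
  sps <- spectro_pair(512)
  geom <- list(n_bscans = 2, n_ascans = 16)
  v1 <- simulate_volume(thin_phantom(), dispersion_truth(), geom,
                        default_source, sps, seed = 42)
  v2 <- simulate_volume(thin_phantom(), dispersion_truth(), geom,
                        default_source, sps, seed = 42)
  v3 <- simulate_volume(thin_phantom(), dispersion_truth(), geom,
                        default_source, sps, seed = 43)
  expect_identical(v1$co, v2$co)
  expect_identical(v1$cross, v2$cross)
  expect_identical(v1$truth$surface_um, v2$truth$surface_um)
  expect_false(identical(v1$co, v3$co))
})

test_that("zero motion and a flat surface give a constant ground-truth surface", {
  sps <- spectro_pair(512)
  v <- simulate_volume(thin_phantom(surface_ripple_um = 0,
                                    surface_jitter_um = 0),
                       dispersion_truth(), list(n_bscans = 3, n_ascans = 12),
                       default_source, sps, motion_um = 0, seed = 1)
  expect_equal(max(v$truth$surface_um) - min(v$truth$surface_um), 0)
})

test_that("calibration fringes carry the channel mapping in their phase", {
  sp_co <- spectrometer_model(1024, "co")
  # identical channel models -> identical fringes
  fr <- simulate_calibration_fringes(list(a = sp_co, b = sp_co), 400)
  expect_identical(fr$a, fr$b)
  # known mapping: analytic-signal phase reproduces 2 k(p) z up to offset
  z <- 400
  phi <- signal::unwrap(Arg(analytic_signal(fr$a - mean(fr$a))))
  truth <- 2 * spectrometer_wavenumbers(sp_co) * z
  idx <- 103:922  # central 80%: envelope edges excluded
  resid <- (phi[idx] - mean(phi[idx])) - (-(truth[idx] - mean(truth[idx])))
  expect_lt(max(abs(resid)), 0.05)  # rad, out of ~800 rad of fringe phase
})

test_that("linear-in-k sampling gives fringe phase linear in pixel index", {
  n <- 1024
  k_lin <- seq(7.9, 7.1, length.out = n)
  env <- source_envelope(default_source, k_lin)
  fringe <- env * cos(2 * k_lin * 350)
  phi <- signal::unwrap(Arg(analytic_signal(fringe - mean(fringe))))
  idx <- 103:922
  fit <- lm(phi[idx] ~ idx)
  # small residual ripple comes from the envelope edges entering the
  # discrete analytic-signal construction; ~800 rad of phase total
  expect_lt(max(abs(residuals(fit))), 0.02)
})

test_that("texture correlation width tracks the requested correlation length", {
  # oracle: autocorrelation of the generated ground-truth (zero-mean)
  # field itself, before any OCT encoding
  acf_width <- function(f) {
    M <- normalized_autocorrelation(f)
    cs <- M[, (ncol(M) + 1L) %/% 2L]
    cs[(length(cs) + 1L) %/% 2L] <- 1
    measure_fwhm(cs)
  }
  set.seed(301)
  w1 <- mean(replicate(4, acf_width(psoct:::gaussian_random_field(256, 256, 3))))
  set.seed(302)
  w2 <- mean(replicate(4, acf_width(psoct:::gaussian_random_field(256, 256, 6))))
  expect_lt(abs(w2 / w1 - 2), 0.15 * 2)
})

test_that("texture sheets follow the phantom's depth laws", {
  spec <- phantom_spec()
  expect_equal(texture_corr_length_um(spec, 0), spec$corr_len_range[1])
  expect_equal(texture_corr_length_um(spec, 1), spec$corr_len_range[2])
  expect_true(all(diff(texture_corr_length_um(spec, seq(0, 1, 0.1))) >= 0))
  expect_true(all(diff(texture_amplitude_at(spec, seq(0, 1, 0.1))) <= 0))
  expect_error(phantom_spec(cross_fraction = c(epithelium = 0.2, bowman = 0,
                                               stroma = 0.5, descemet = 0,
                                               endothelium = 0)),
               "polarization")
})
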