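test_that("the phase term is the identity at zero and inverts under negation", {
  sp <- spectrometer_model(512, "co")
  cal <- calibration_from_models(list(co = sp))
  k <- cal$k_grid
  s <- mirror_spectrum(300, 0, sp, cal, channel = "co")
  expect_lt(max(abs(apply_phase(s, k, 0, 0) - s)), 1e-10 * max(abs(s)))
  # round trip: exact in the continuum; the discrete real-part path
  # leaks a small fraction of the windowed chirp kernel's tails
  round_trip <- apply_phase(apply_phase(s, k, 7.5, 0), k, -7.5, 0)
  expect_lt(max(abs(round_trip - s)), 0.01 * max(abs(s)))
  a0 <- ascan_from_spectrum(s)
  expect_equal(max(ascan_from_spectrum(round_trip)), max(a0),
               tolerance = 0.005)
  expect_error(apply_phase(s, k^1.01, 1), "uniform")
})

test_that("compensating with the negative coefficient restores the transform-limited width", {
  sp <- spectrometer_model(1024, "co")
  cal <- calibration_from_models(list(co = sp))
  f0 <- psf_fwhm_um(mirror_spectrum(400, 0, sp, cal, channel = "co"), cal)
  for (a2 in c(5, 15)) {
    s <- mirror_spectrum(400, a2, sp, cal, channel = "co")
    sc <- apply_phase(s, cal$k_grid, -a2, 0, k0 = default_source$k0)
    expect_lt(abs(psf_fwhm_um(sc, cal) - f0) / f0, 0.02)
  }
})

test_that("A-scan formation resolves reflectors linearly and conserves energy", {
  sp <- spectrometer_model(1024, "co")
  cal <- calibration_from_models(list(co = sp))
  # two equal reflectors, well separated: two equal peaks
  fr <- simulate_fringe(data.frame(depth_um = c(200, 450),
                                   amplitude = c(0.3, 0.3)),
                        default_source, sp, dc_level = 0)
  s <- resample_to_k(fr, cal, "co"); s <- s - mean(s)
  a <- ascan_from_spectrum(s)
  L <- attr(a, "fft_length")
  zax <- depth_axis_um(length(a), cal$dk, attr(a, "fft_length"))
  # windowed energy per reflector (peak-bin heights scallop on the
  # discrete depth grid; the energy under each peak does not)
  e1 <- sum(a[zax > 150 & zax < 250])
  e2 <- sum(a[zax > 400 & zax < 500])
  expect_lt(abs(e1 - e2) / max(e1, e2), 0.01)
  # Parseval: A-scan intensity sums to half the (padded) spectral energy
  expect_equal(sum(a), L * sum(s^2) / 2, tolerance = 0.01)
})

test_that("the a2 search recovers known dispersion to within one grid step", {
  sp <- spectrometer_model(1024, "co")
  cal <- calibration_from_models(list(co = sp))
  k <- cal$k_grid
  cfg <- dispersion_search_config(source = default_source, k = k)
  step <- diff(cfg$a2_range) / (cfg$n_steps - 1)
  for (a2_true in c(-12, 0, 7, 18)) {
    s <- mirror_spectrum(350, a2_true, sp, cal, channel = "co")
    r <- search_a2(s, k, cfg)
    expect_lte(abs(r$best_a2 + a2_true), step * 1.0001)
    expect_false(r$low_contrast)
  }
  # metric curve is unimodal: no secondary maximum above 90% of the peak
  s <- mirror_spectrum(350, 10, sp, cal, channel = "co")
  r <- search_a2(s, k, cfg)
  m <- r$metric
  local_max <- which(diff(sign(diff(m))) == -2) + 1L
  big <- local_max[m[local_max] > 0.9 * max(m)]
  expect_true(all(abs(r$a2_values[big] + 10) < 3 * step))
  # an all-noise spectrum is flagged as low contrast
  set.seed(51)
  rn <- search_a2(rnorm(length(k), sd = 1e-3), k, cfg)
  expect_true(rn$low_contrast)
})

test_that("PSF degradation grows monotonically with residual dispersion", {
  sp <- spectrometer_model(1024, "co")
  cal <- calibration_from_models(list(co = sp))
  s <- mirror_spectrum(400, 0, sp, cal, channel = "co")
  fw <- vapply(c(0, 2, 4, 8, 16, 24), function(res)
    psf_fwhm_um(apply_phase(s, cal$k_grid, res, 0, k0 = default_source$k0),
                cal), 0)
  expect_true(all(diff(fw) >= -1e-6))
})

test_that("polynomial profile fitting reproduces exact polynomials and denoises", {
  t_idx <- seq_len(1024)
  tt <- seq(-1, 1, length.out = 1024)
  truth <- 3 + 2 * tt - 5 * tt^3 + 1.5 * tt^5
  fit <- fit_profile(truth, 5)
  expect_equal(fit$fitted, truth, tolerance = 1e-9)
  expect_equal(fit_profile(rep(4, 100), 5)$fitted, rep(4, 100),
               tolerance = 1e-9)
  expect_error(fit_profile(c(1, 2, 3), 5), "order")
  # noise reduction: fitted RMSE < raw RMSE (seeded Monte Carlo)
  set.seed(52)
  step <- 0.265
  for (i in 1:5) {
    raw <- truth + rnorm(1024, sd = 2 * step)
    f <- fit_profile(raw, 5)
    expect_lt(sqrt(mean((f$fitted - truth)^2)),
              sqrt(mean((raw - truth)^2)))
  }
})

test_that("B-scan compensation recovers a smooth scan-dependent profile and transfers to the cross channel", {
  sps <- spectro_pair(1024)
  cal <- calibration_from_models(sps)
  truth <- dispersion_truth(a2_coef = c(3, -2, 9))   # order-2 scan dependence
  raw <- simulate_volume(phantom_spec(), truth,
                         list(n_bscans = 1, n_ascans = 96),
                         default_source, sps, seed = 53)
  co <- subtract_mean_spectrum(resample_to_k(raw$co[1, , ], cal, "co"))
  cr <- subtract_mean_spectrum(resample_to_k(raw$cross[1, , ], cal, "cross"))
  cfg <- dispersion_search_config(source = default_source, k = cal$k_grid)
  res <- compensate_bscan(co, cr, cal$k_grid, cfg)
  step <- diff(cfg$a2_range) / (cfg$n_steps - 1)
  expect_lt(max(abs(res$profile$fitted + raw$truth$a2)), 2 * step)
  expect_equal(dim(res$co), dim(res$cross))
  # raw per-A-scan optima are retained for diagnostics
  expect_length(res$profile$raw, 96)
})

test_that("a search range that excludes the truth saturates at the boundary and warns", {
  sps <- spectro_pair(1024)
  cal <- calibration_from_models(sps)
  raw <- simulate_volume(phantom_spec(), dispersion_truth(a2_coef = c(15)),
                         list(n_bscans = 1, n_ascans = 16),
                         default_source, sps, seed = 54)
  co <- subtract_mean_spectrum(resample_to_k(raw$co[1, , ], cal, "co"))
  cr <- subtract_mean_spectrum(resample_to_k(raw$cross[1, , ], cal, "cross"))
  cfg <- dispersion_search_config(a2_range = c(-5, 5), n_steps = 30,
                                  polynomial_order = 2,
                                  source = default_source)
  expect_warning(compensate_bscan(co, cr, cal$k_grid, cfg), "boundary")
})
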