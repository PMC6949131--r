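#' Dispersion search configuration
#'
#' Parameters of the per-A-scan search for the second-order dispersion
#' compensation coefficient. The coefficient `a2` (rad/(rad/um)^2) weights
#' a quadratic-in-wavenumber phase term added to the analytic spectrum;
#' the search evaluates `n_steps` equally spaced values over `a2_range`
#' and keeps, per A-scan, the value maximising the A-scan's peak
#' intensity. The per-A-scan optima are then smoothed by a polynomial fit
#' of order `polynomial_order` in A-scan index.
#'
#' @param a2_range numeric `c(min, max)`; defaults to plus/minus the
#'   coefficient that broadens the transform-limited PSF of `source`
#'   five-fold (see [a2_for_broadening()]).
#' @param n_steps number of search values (default 200).
#' @param k0 center wavenumber (rad/um) of the phase expansion.
#' @param dc_exclusion_depth depth pixels (pre-padding scale) excluded
#'   around zero delay when taking the peak metric (default 10).
#' @param polynomial_order order of the smoothing fit (default 5).
#' @param search_a3 logical; also search a third-order coefficient
#'   (off by default: its optimum is approximately 0 for this system).
#' @param a3_range,a3_steps third-order search grid when `search_a3`.
#' @param source a [source_spectrum()] used for the default range.
#' @param k optional uniform wavenumber grid; when given, the default
#'   range accounts for the sampled (possibly truncated) spectral shape
#'   via [a2_for_broadening_sampled()] instead of the Gaussian closed
#'   form.
#' @return object of class `psoct_search_config`.
#' @export
dispersion_search_config <- function(a2_range = NULL, n_steps = 200,
                                     k0 = NULL,
                                     dc_exclusion_depth = 10,
                                     polynomial_order = 5,
                                     search_a3 = FALSE,
                                     a3_range = NULL, a3_steps = 21,
                                     source = source_spectrum(),
                                     k = NULL) {
  if (is.null(a2_range)) {
    a <- if (is.null(k)) a2_for_broadening(source, factor = 5)
         else a2_for_broadening_sampled(source, k, factor = 5)
    a2_range <- c(-a, a)
  }
  if (is.null(k0)) k0 <- source$k0
  stopifnot(n_steps >= 2, a2_range[1] < a2_range[2],
            dc_exclusion_depth >= 0, polynomial_order >= 0)
  if (is.null(a3_range)) a3_range <- a2_range / source$sigma_k
  structure(list(a2_range = a2_range, n_steps = as.integer(n_steps),
                 k0 = k0, dc_exclusion_depth = dc_exclusion_depth,
                 polynomial_order = as.integer(polynomial_order),
                 search_a3 = isTRUE(search_a3), a3_range = a3_range,
                 a3_steps = as.integer(a3_steps)),
            class = "psoct_search_config")
}

#' Second-order coefficient producing a given PSF broadening
#'
#' For a Gaussian spectrum with wavenumber standard deviation `sigma_k`, a
#' residual quadratic phase `a2 (k-k0)^2` broadens the transform-limited
#' PSF by `sqrt(1 + (2 a2 sigma_k^2)^2)`; inverting gives the `a2` that
#' broadens it by `factor`.
#' @param source a [source_spectrum()].
#' @param factor broadening factor (> 1).
#' @export
a2_for_broadening <- function(source, factor = 5) {
  stopifnot(factor > 1)
  sqrt(factor^2 - 1) / (2 * source$sigma_k^2)
}

#' Broadening coefficient for a sampled (truncated) spectrum
#'
#' Spectrometers usually truncate the source tails, which reduces the
#' effective spectral width and hence the PSF broadening a given `a2`
#' produces. This variant measures broadening numerically on the sampled
#' envelope: FWHM of the magnitude PSF of `S(k) exp(i a2 (k-k0)^2)`
#' relative to `a2 = 0`, solved for the requested factor by bisection.
#'
#' @inheritParams a2_for_broadening
#' @param k uniform wavenumber grid (rad/um) on which the spectrum is
#'   sampled.
#' @export
a2_for_broadening_sampled <- function(source, k, factor = 5) {
  stopifnot(factor > 1)
  env <- source_envelope(source, k)
  n <- length(k)
  L <- 8L * stats::nextn(n, 2)
  z0 <- pi / (4 * (k[2] - k[1]))   # carrier placing the PSF mid-range
  fwhm_at <- function(a2) {
    s <- env * exp(1i * (2 * k * z0 + a2 * (k - source$k0)^2))
    measure_fwhm(Mod(stats::fft(c(s, complex(L - n)))[seq_len(L %/% 2L)]))
  }
  f0 <- fwhm_at(0)
  lo <- 0; hi <- a2_for_broadening(source, factor)
  while (fwhm_at(hi) / f0 < factor) hi <- 2 * hi
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (fwhm_at(mid) / f0 < factor) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Apply a numerical dispersion-compensation phase to a spectrum
#'
#' Generates the complex analytic spectrum (Hilbert construction),
#' multiplies it by `exp(i (a2 (k-k0)^2 + a3 (k-k0)^3))` and returns the
#' real part. With `a2 = a3 = 0` the input is returned unchanged to
#' numerical tolerance; applying `a2` then `-a2` round-trips.
#'
#' @param spectrum real spectral vector on a uniform k grid (or matrix
#'   with spectra in columns).
#' @param k uniform wavenumber grid (rad/um).
#' @param a2 second-order coefficient, rad/(rad/um)^2.
#' @param a3 third-order coefficient, rad/(rad/um)^3.
#' @param k0 center wavenumber; default mid-grid.
#' @return phase-corrected real spectrum, same shape as input.
#' @export
apply_phase <- function(spectrum, k, a2, a3 = 0, k0 = NULL) {
  dkk <- diff(k)
  if (max(dkk) - min(dkk) > 1e-6 * abs(mean(dkk)))
    stop("wavenumber grid must be uniform")
  if (is.null(k0)) k0 <- k[1] + (k[length(k)] - k[1]) / 2
  ph <- exp(1i * (a2 * (k - k0)^2 + a3 * (k - k0)^3))
  if (is.matrix(spectrum)) {
    stopifnot(nrow(spectrum) == length(k))
    Re(analytic_signal_matrix(spectrum) * ph)
  } else {
    stopifnot(length(spectrum) == length(k))
    Re(analytic_signal(spectrum) * ph)
  }
}

#' Reconstruct an intensity A-scan from a phase-corrected spectrum
#'
#' Fast Fourier transform of the real-valued phase-corrected spectrum,
#' zero-padded to [reconstruction_fft_length()]; returns the squared
#' magnitude of the positive-frequency half.
#'
#' @param spectrum real spectral vector (mean-subtracted), or matrix with
#'   spectra in columns.
#' @param pad logical; zero-pad (default TRUE).
#' @return intensity A-scan of length `fft_length/2` (or matrix thereof,
#'   A-scans in columns), with attribute `fft_length`.
#' @export
ascan_from_spectrum <- function(spectrum, pad = TRUE) {
  if (is.matrix(spectrum)) {
    n <- nrow(spectrum)
    L <- if (pad) reconstruction_fft_length(n) else n
    padded <- rbind(spectrum, matrix(0, L - n, ncol(spectrum)))
    out <- Mod(stats::mvfft(padded)[seq_len(L %/% 2L), , drop = FALSE])^2
  } else {
    n <- length(spectrum)
    L <- if (pad) reconstruction_fft_length(n) else n
    out <- Mod(stats::fft(c(spectrum, numeric(L - n)))[seq_len(L %/% 2L)])^2
  }
  attr(out, "fft_length") <- L
  out
}

# Peak metric: maximum intensity over depth, excluding the DC region.
# The peak height is refined by parabolic interpolation of the
# log-intensity across the maximum bin and its neighbors (exact for a
# Gaussian-shaped peak), suppressing the scalloping of the discrete
# depth grid: the true peak generally falls between bins.
peak_metric <- function(ascan_mat, dc_excl_bins) {
  if (!is.matrix(ascan_mat)) ascan_mat <- matrix(ascan_mat, ncol = 1)
  lo <- min(dc_excl_bins + 1L, nrow(ascan_mat))
  m <- ascan_mat[lo:nrow(ascan_mat), , drop = FALSE]
  nr <- nrow(m)
  i <- max.col(t(m), ties.method = "first")
  h <- m[cbind(i, seq_len(ncol(m)))]
  interior <- i > 1L & i < nr & h > 0
  if (any(interior)) {
    ii <- i[interior]; jj <- which(interior)
    l1 <- log(pmax(m[cbind(ii - 1L, jj)], .Machine$double.xmin))
    l2 <- log(h[interior])
    l3 <- log(pmax(m[cbind(ii + 1L, jj)], .Machine$double.xmin))
    den <- l1 - 2 * l2 + l3
    ok <- den < 0
    hh <- h[interior]
    hh[ok] <- exp(l2[ok] - (l1[ok] - l3[ok])^2 / (8 * den[ok]))
    h[interior] <- hh
  }
  h
}

#' Search the optimal second-order dispersion coefficient of one A-scan
#'
#' Evaluates, for each of `n_steps` equally spaced `a2` values over
#' `a2_range`, the peak intensity of the reconstructed A-scan (maximum
#' over depth, excluding the DC-adjacent region), and returns the argmax.
#' Exact ties are broken toward the smallest `|a2|` (minimal-correction
#' prior). A flat metric curve (max/median contrast below 2) is flagged as
#' `low_contrast`, indicating an all-noise spectrum.
#'
#' @param spectrum real mean-subtracted spectral vector on the uniform
#'   grid `k`.
#' @param k uniform wavenumber grid (rad/um).
#' @param config a [dispersion_search_config()].
#' @return list: `best_a2`, `a2_values`, `metric`, `low_contrast`.
#' @export
search_a2 <- function(spectrum, k, config = dispersion_search_config()) {
  a2v <- seq(config$a2_range[1], config$a2_range[2],
             length.out = config$n_steps)
  a <- analytic_signal(spectrum)
  dk0 <- k - config$k0
  n <- length(k)
  L <- reconstruction_fft_length(n)
  excl <- ceiling(config$dc_exclusion_depth * L / n)
  metric <- vapply(a2v, function(a2) {
    s <- Re(a * exp(1i * a2 * dk0^2))
    peak_metric(ascan_from_spectrum(s), excl)
  }, 0)
  mx <- max(metric)
  ties <- which(metric == mx)
  best <- ties[which.min(abs(a2v[ties]))]
  list(best_a2 = a2v[best], a2_values = a2v, metric = metric,
       low_contrast = (mx / stats::median(metric)) < 2)
}

#' Fit the per-A-scan dispersion profile with a polynomial
#'
#' Least-squares polynomial fit (default order 5) of the raw per-A-scan
#' optimum `a2` against A-scan index, eliminating the noise-driven
#' fluctuation of the individual optima.
#'
#' @param raw_a2 raw per-A-scan best coefficients.
#' @param order polynomial order (default 5).
#' @return object of class `psoct_dispersion_profile`: `raw`, `fitted`,
#'   `coefficients` (ascending, in the centered index coordinate), `order`.
#' @export
fit_profile <- function(raw_a2, order = 5) {
  n <- length(raw_a2)
  if (n < order + 1L)
    stop("need at least order+1 A-scans to fit the dispersion profile")
  t <- seq(-1, 1, length.out = n)
  X <- outer(t, 0:order, `^`)
  cf <- qr.coef(qr(X), raw_a2)
  cf[is.na(cf)] <- 0
  structure(list(raw = raw_a2, fitted = as.numeric(X %*% cf),
                 coefficients = as.numeric(cf), order = order),
            class = "psoct_dispersion_profile")
}

#' Dispersion-compensate one B-scan of both polarization channels
#'
#' Runs the per-A-scan `a2` search on the co-polarized channel only, fits
#' the resulting profile with a polynomial of order
#' `config$polynomial_order`, applies the fitted per-A-scan coefficients
#' to both channels, and reconstructs the final intensity images. If half
#' or more of the raw optima sit on the search-range boundary, a warning
#' reports probable range misconfiguration.
#'
#' @param co_bscan,cross_bscan mean-subtracted spectra (A-scans in rows)
#'   on the common uniform grid `k`.
#' @param k uniform wavenumber grid (rad/um).
#' @param config a [dispersion_search_config()].
#' @return list: `co`, `cross` intensity images (depth in rows, A-scans in
#'   columns), `profile` ([fit_profile()] result with the raw search
#'   optima retained for diagnostics), `low_contrast` logical per A-scan.
#' @export
compensate_bscan <- function(co_bscan, cross_bscan, k,
                             config = dispersion_search_config()) {
  stopifnot(is.matrix(co_bscan), is.matrix(cross_bscan),
            ncol(co_bscan) == length(k), ncol(cross_bscan) == length(k),
            nrow(co_bscan) == nrow(cross_bscan))
  na <- nrow(co_bscan)
  n <- length(k)
  a2v <- seq(config$a2_range[1], config$a2_range[2],
             length.out = config$n_steps)
  dk0 <- k - config$k0
  L <- reconstruction_fft_length(n)
  excl <- ceiling(config$dc_exclusion_depth * L / n)

  A <- analytic_signal_matrix(t(co_bscan))    # k in rows, A-scans in cols
  metric <- matrix(0, config$n_steps, na)
  for (i in seq_along(a2v)) {
    s <- Re(A * exp(1i * a2v[i] * dk0^2))
    metric[i, ] <- peak_metric(ascan_from_spectrum(s), excl)
  }
  raw <- numeric(na)
  low <- logical(na)
  for (x in seq_len(na)) {
    mx <- max(metric[, x])
    ties <- which(metric[, x] == mx)
    raw[x] <- a2v[ties[which.min(abs(a2v[ties]))]]
    low[x] <- (mx / stats::median(metric[, x])) < 2
  }
  at_edge <- mean(raw == a2v[1] | raw == a2v[config$n_steps])
  if (at_edge >= 0.5)
    warning(sprintf(
      "%.0f%% of per-A-scan optima lie on the a2 search boundary; widen a2_range",
      100 * at_edge))
  prof <- fit_profile(raw, config$polynomial_order)

  Across <- analytic_signal_matrix(t(cross_bscan))
  phase <- exp(1i * outer(dk0^2, prof$fitted))
  co_img <- ascan_from_spectrum(Re(A * phase))
  cross_img <- ascan_from_spectrum(Re(Across * phase))
  list(co = co_img, cross = cross_img, profile = prof, low_contrast = low)
}
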