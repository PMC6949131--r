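#' Derive a pixel-to-wavenumber mapping from a calibration fringe
#'
#' A mirror-terminated Michelson fringe `S(k) cos(2 k z)` sampled on the
#' spectrometer's pixel grid carries the mapping in its phase: the
#' analytic-signal phase, unwrapped, satisfies `phi(p) = +-2 k(p) z + c`.
#' The phase is fitted with a low-order polynomial over the well-modulated
#' part of the spectrum (envelope above the `envelope_cut` quantile of its
#' maximum), extrapolated to the edges by the fit, converted to wavenumber
#' by `k = phi/(2 z)`, and anchored in absolute terms by placing the
#' envelope peak at the nominal center wavenumber `2*pi/lambda0`.
#'
#' @param fringe calibration fringe vector.
#' @param mirror_delay_um single-pass optical delay of the auxiliary
#'   interferometer (um).
#' @param lambda0_nm nominal center wavelength (nm) used to fix the
#'   absolute offset of the mapping.
#' @param fit_order polynomial order of the phase fit (default 3).
#' @param envelope_cut fraction of the envelope maximum below which pixels
#'   are excluded from the fit (default 0.05).
#' @param k_decreasing logical; wavelength increases with pixel index so k
#'   decreases (default), used to orient the phase slope.
#' @return numeric vector: wavenumber (rad/um) per pixel, strictly
#'   monotone.
#' @export
derive_mapping <- function(fringe, mirror_delay_um, lambda0_nm = 840,
                           fit_order = 3, envelope_cut = 0.05,
                           k_decreasing = TRUE) {
  stopifnot(mirror_delay_um > 0, fit_order >= 1)
  np <- length(fringe)
  a <- analytic_signal(fringe - mean(fringe))
  envl <- Mod(a)
  keep <- envl >= envelope_cut * max(envl)
  # restrict to the contiguous central run around the envelope peak
  ipk <- which.max(envl)
  lo <- ipk; while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- ipk; while (hi < np && keep[hi + 1L]) hi <- hi + 1L
  if (hi - lo < 8L * (fit_order + 1L))
    stop("calibration fringe has too few well-modulated pixels")
  phi <- signal::unwrap(Arg(a[lo:hi]))
  if (stats::sd(diff(phi)) > abs(mean(diff(phi))))
    stop("calibration failure: unwrapped fringe phase is not monotone")
  t <- seq(0, 1, length.out = np)
  fit <- stats::lm(phi ~ stats::poly(t[lo:hi], fit_order, raw = TRUE))
  phi_all <- as.numeric(cbind(1, stats::poly(t, fit_order, raw = TRUE)) %*%
                          stats::coef(fit))
  slope_sign <- sign(mean(diff(phi_all)))
  want_sign <- if (k_decreasing) -1 else 1
  k_rel <- want_sign * slope_sign * phi_all / (2 * mirror_delay_um)
  # absolute anchor: envelope peak (sub-pixel, quadratic on log-envelope)
  ppk <- ipk
  if (ipk > 1L && ipk < np) {
    le <- log(pmax(envl[(ipk - 1L):(ipk + 1L)], .Machine$double.eps))
    den <- le[1] - 2 * le[2] + le[3]
    if (den < 0) ppk <- ipk + 0.5 * (le[1] - le[3]) / den
  }
  k_at_peak <- stats::approx(seq_len(np), k_rel, xout = ppk)$y
  k <- k_rel - k_at_peak + 2 * pi / (lambda0_nm / 1000)
  if (any(diff(k) == 0))
    stop("calibration failure: derived mapping is not strictly monotone")
  k
}

#' Build a calibration map for the two polarization channels
#'
#' Combines per-channel pixel-to-wavenumber mappings into one object with
#' a common uniform k grid, contained in the intersection of both
#' channels' spectral supports, onto which all spectra are resampled.
#'
#' @param mappings named list (`co`, `cross`) of per-pixel wavenumber
#'   vectors (as from [derive_mapping()] or
#'   [spectrometer_wavenumbers()]).
#' @param n_grid number of points of the common uniform grid; defaults to
#'   the pixel count.
#' @param lambda0_nm nominal center wavelength, stored as `k0`.
#' @return object of class `psoct_calibration`: `mappings`, `k_grid`
#'   (ascending, uniform), `dk`, `k0`.
#' @export
calibration_map <- function(mappings, n_grid = NULL, lambda0_nm = 840) {
  stopifnot(is.list(mappings), length(mappings) >= 1)
  for (m in mappings) {
    d <- diff(m)
    if (!(all(d > 0) || all(d < 0)))
      stop("each channel mapping must be strictly monotone")
  }
  if (is.null(n_grid)) n_grid <- length(mappings[[1]])
  k_lo <- max(vapply(mappings, min, 0))
  k_hi <- min(vapply(mappings, max, 0))
  if (k_hi <= k_lo) stop("channel k supports do not overlap")
  k_grid <- seq(k_lo, k_hi, length.out = n_grid)
  k0 <- 2 * pi / (lambda0_nm / 1000)
  if (k0 < k_lo || k0 > k_hi)
    stop("center wavenumber k0 lies outside the common grid")
  structure(list(mappings = mappings, k_grid = k_grid,
                 dk = k_grid[2] - k_grid[1], k0 = k0),
            class = "psoct_calibration")
}

#' Identity calibration from the spectrometer models themselves
#'
#' Uses the true pixel-to-wavenumber mappings of the given spectrometer
#' models (bypassing fringe-based derivation); convenient for simulations
#' and oracle tests.
#' @param spectrometers named list of [spectrometer_model()]s.
#' @param n_grid common grid length (default: pixel count).
#' @param lambda0_nm nominal center wavelength.
#' @export
calibration_from_models <- function(spectrometers, n_grid = NULL,
                                    lambda0_nm = 840) {
  calibration_map(lapply(spectrometers, spectrometer_wavenumbers),
                  n_grid = n_grid, lambda0_nm = lambda0_nm)
}

#' Resample a spectrum onto the common uniform k grid
#'
#' Interpolates spectral samples taken at the channel's (nonlinear)
#' wavenumbers onto the calibration's uniform grid. Cubic-spline
#' interpolation by default; values outside the channel support are set to
#' zero. After this step both channels live on the identical grid, so a
#' common reflector produces peaks at identical depth pixels.
#'
#' @param spectrum spectral vector (or matrix with spectra in rows).
#' @param calibration a [calibration_map()].
#' @param channel which channel's mapping to use.
#' @param method `"spline"` (default) or `"linear"`.
#' @return vector (or matrix) on the uniform k grid.
#' @export
resample_to_k <- function(spectrum, calibration, channel = "co",
                          method = c("spline", "linear")) {
  method <- match.arg(method)
  map <- calibration$mappings[[channel]]
  if (is.null(map)) stop("unknown channel: ", channel)
  one <- function(v) {
    if (length(v) != length(map))
      stop("spectrum length does not match the channel mapping")
    o <- order(map)
    kk <- map[o]; vv <- v[o]
    out <- if (method == "spline") {
      stats::spline(kk, vv, xout = calibration$k_grid, method = "fmm")$y
    } else {
      stats::approx(kk, vv, xout = calibration$k_grid, rule = 2)$y
    }
    out[calibration$k_grid < kk[1] | calibration$k_grid > kk[length(kk)]] <- 0
    out
  }
  if (is.matrix(spectrum)) t(apply(spectrum, 1, one)) else one(spectrum)
}
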