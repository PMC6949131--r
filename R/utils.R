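#' Analytic signal of a real vector
#'
#' Computes the complex analytic signal by zeroing the negative-frequency
#' half of the DFT and doubling the positive half (DC and Nyquist bins are
#' kept with unit weight), i.e. the discrete Hilbert-transform construction.
#' The real part of the result equals the input to machine precision.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1
    w[n / 2L + 1L] <- 1
    w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1
    w[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

#' Analytic signal of each column of a matrix
#'
#' Column-wise [analytic_signal()] using a single multi-column FFT.
#'
#' @param m real numeric matrix (signals in columns).
#' @return complex matrix of the same dimensions.
#' @export
analytic_signal_matrix <- function(m) {
  n <- nrow(m)
  X <- stats::mvfft(m)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1L] <- 1; w[n / 2L + 1L] <- 1; w[2L:(n / 2L)] <- 2
  } else {
    w[1L] <- 1; w[2L:((n + 1L) / 2L)] <- 2
  }
  stats::mvfft(X * w, inverse = TRUE) / n
}

#' Full width at half maximum of a sampled peak
#'
#' Locates the global maximum of `y` and the two half-maximum crossings
#' around it by linear interpolation between samples, returning their
#' distance in units of `x` (or in sample spacing if `x` is missing).
#'
#' @param y non-negative numeric vector containing a single dominant peak.
#' @param x optional abscissa (same length, uniformly increasing).
#' @return FWHM as a scalar; `NA` if a half crossing is not bracketed.
#' @export
measure_fwhm <- function(y, x = NULL) {
  n <- length(y)
  if (is.null(x)) x <- seq_len(n) - 1
  i0 <- which.max(y)
  half <- y[i0] / 2
  # walk left
  il <- i0
  while (il > 1L && y[il - 1L] > half) il <- il - 1L
  if (il == 1L) return(NA_real_)
  xl <- x[il - 1L] + (x[il] - x[il - 1L]) * (half - y[il - 1L]) / (y[il] - y[il - 1L])
  # walk right
  ir <- i0
  while (ir < n && y[ir + 1L] > half) ir <- ir + 1L
  if (ir == n) return(NA_real_)
  xr <- x[ir] + (x[ir + 1L] - x[ir]) * (half - y[ir]) / (y[ir + 1L] - y[ir])
  xr - xl
}

#' Depth axis of a reconstructed A-scan
#'
#' For spectra sampled uniformly in wavenumber with spacing `dk` (rad/um)
#' and Fourier-transformed at length `fft_length`, depth bin `m` (0-based)
#' corresponds to an optical path depth of `pi * m / (fft_length * dk)` um.
#'
#' @param n_out number of depth bins returned (positive-frequency half).
#' @param dk wavenumber sample spacing, rad/um.
#' @param fft_length FFT length used for reconstruction.
#' @return numeric vector of optical depths in um.
#' @export
depth_axis_um <- function(n_out, dk, fft_length) {
  pi * (seq_len(n_out) - 1) / (fft_length * dk)
}

#' Convert an optical depth in um to a (0-based) depth bin
#' @inheritParams depth_axis_um
#' @param z_um optical path depth in um.
#' @export
um_to_depth_bin <- function(z_um, dk, fft_length) {
  z_um * fft_length * dk / pi
}

#' FFT length used for A-scan reconstruction
#'
#' Next power of two at least twice the spectral length, so peaks are
#' localised on a grid twice as fine as the intrinsic depth sampling.
#' @param n spectral length.
#' @export
reconstruction_fft_length <- function(n) {
  stats::nextn(2L * n, 2L)
}

# Evaluate a polynomial with ascending coefficients at x.
polyval_asc <- function(coef, x) {
  y <- numeric(length(x)) + coef[length(coef)]
  if (length(coef) > 1L) {
    for (i in (length(coef) - 1L):1L) y <- y * x + coef[i]
  } else {
    y <- rep(coef, length.out = length(x))
  }
  y
}
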