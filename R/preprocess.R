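#' Subtract the mean spectrum of a B-scan
#'
#' Removes the DC term and fixed-pattern noise by subtracting the averaged
#' (mean) spectrum of all A-scans within a B-scan from each spectrum. Any
#' additive spectral component common to all A-scans of the B-scan is
#' removed exactly; after the operation every spectral column has zero
#' mean across A-scans.
#'
#' Applied per B-scan and per channel independently (the two channels are
#' recorded by separate spectrometers).
#'
#' @param bscan matrix of spectra, A-scans in rows.
#' @return matrix of the same shape with the column means removed.
#' @export
subtract_mean_spectrum <- function(bscan) {
  stopifnot(is.matrix(bscan), all(is.finite(bscan)))
  if (nrow(bscan) < 2L)
    warning("B-scan has a single A-scan; mean subtraction is degenerate")
  sweep(bscan, 2L, colMeans(bscan))
}
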