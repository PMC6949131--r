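# Shared desk-scale fixtures. All simulated at run time; no stored data.

default_source <- source_spectrum()

# 1024-pixel spectrometer pair: deep enough (unambiguous range ~1.4 mm)
# for the full corneal phantom.
spectro_pair <- function(n_pixels = 1024) {
  list(co = spectrometer_model(n_pixels, "co"),
       cross = spectrometer_model(n_pixels, "cross"))
}

# Wide-span spectrometer that captures essentially the whole Gaussian
# envelope (+-3 sigma), for tests against transform-limited closed forms.
wide_spectrometer <- function(n_pixels = 2048) {
  spectrometer_model(n_pixels, "co", lambda_coef = c(0.715, 0.290))
}

# A thin-cornea phantom that fits in a 512-pixel depth range; used where
# full depth is not the point and speed matters.
thin_phantom <- function(...) {
  phantom_spec(thickness_um = c(epithelium = 48, bowman = 15, stroma = 200,
                                descemet = 10, endothelium = 5),
               surface_depth_um = 80, ...)
}

# Resampled, mean-free spectrum of a single mirror observed through a
# spectrometer channel with sample dispersion a2.
mirror_spectrum <- function(z_um, a2, spectrometer, calibration,
                            channel = spectrometer$channel,
                            amplitude = 0.5, source = default_source) {
  fr <- simulate_fringe(data.frame(depth_um = z_um, amplitude = amplitude),
                        source, spectrometer, dispersion = c(a2, 0),
                        dc_level = 0)
  s <- resample_to_k(fr, calibration, channel)
  s - mean(s)
}

# FWHM (um of optical path) of the magnitude A-scan around its main peak.
psf_fwhm_um <- function(spectrum, calibration) {
  a <- sqrt(ascan_from_spectrum(spectrum))
  z <- depth_axis_um(length(a), calibration$dk, attr(a, "fft_length"))
  measure_fwhm(a, z)
}

# FWHM per column of an intensity image (magnitude scale), restricted to
# a window around each column's maximum.
column_fwhm <- function(img, dz, halfwin = 40) {
  vapply(seq_len(ncol(img)), function(j) {
    y <- sqrt(img[, j])
    i <- which.max(y)
    lo <- max(1L, i - halfwin); hi <- min(length(y), i + halfwin)
    measure_fwhm(y[lo:hi], dz * (lo:hi))
  }, 0)
}
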