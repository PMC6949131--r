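#' Broadband source spectrum model
#'
#' Gaussian source centered at `center_wavelength` with the given FWHM
#' bandwidth. The spectral envelope is expressed in wavenumber
#' k = 2*pi/lambda (rad/um): a Gaussian centered at `k0` with FWHM
#' `2*pi*fwhm_bandwidth/center_wavelength^2`.
#'
#' @param center_wavelength center wavelength in nm (default 840).
#' @param fwhm_bandwidth full width at half maximum in nm (default 100).
#' @return object of class `psoct_source` with fields `lambda0_um`,
#'   `dlambda_um`, `k0`, `dk_fwhm`, `sigma_k` (all k quantities in rad/um).
#' @export
source_spectrum <- function(center_wavelength = 840, fwhm_bandwidth = 100) {
  stopifnot(center_wavelength > 0, fwhm_bandwidth > 0,
            fwhm_bandwidth < center_wavelength)
  l0 <- center_wavelength / 1000
  dl <- fwhm_bandwidth / 1000
  k0 <- 2 * pi / l0
  dk <- 2 * pi * dl / l0^2
  structure(list(lambda0_um = l0, dlambda_um = dl, k0 = k0,
                 dk_fwhm = dk, sigma_k = dk / (2 * sqrt(2 * log(2)))),
            class = "psoct_source")
}

#' Source spectral envelope at given wavenumbers
#' @param source a [source_spectrum()].
#' @param k wavenumbers, rad/um.
#' @return amplitude envelope (power spectral density, peak 1).
#' @export
source_envelope <- function(source, k) {
  exp(-(k - source$k0)^2 / (2 * source$sigma_k^2))
}

#' Transform-limited axial resolution of a Gaussian source
#'
#' Closed form `(2*ln 2/pi) * lambda0^2 / dlambda`, in um of optical path
#' (divide by the group index to obtain the value inside tissue, see
#' [resolution_in_tissue()]).
#' @param source a [source_spectrum()].
#' @export
transform_limited_resolution_um <- function(source) {
  2 * log(2) / pi * source$lambda0_um^2 / source$dlambda_um
}

#' Axial resolution inside tissue
#'
#' OCT measures optical path; a resolution measured in air shrinks by the
#' tissue refractive index. With the measured in-air resolution of 4.1 um
#' and the corneal index 1.385 this gives 2.96 um.
#' @param resolution_air_um axial resolution in air, um.
#' @param refractive_index tissue (group) refractive index, default 1.385.
#' @export
resolution_in_tissue <- function(resolution_air_um, refractive_index = 1.385) {
  stopifnot(resolution_air_um > 0, refractive_index >= 1)
  resolution_air_um / refractive_index
}

#' Spectrometer pixel-to-wavelength model
#'
#' The wavelength seen by pixel `p` (0-based) is a polynomial in the
#' normalised coordinate `t = p/(n_pixels-1)`, with ascending coefficients
#' `lambda_coef` in um. Defaults emulate two off-the-shelf spectrometers
#' spanning roughly 783-897 nm whose calibration functions differ in their
#' nonlinear term, as is typical for independently aligned units.
#'
#' @param n_pixels number of camera pixels (default 2048).
#' @param channel `"co"` or `"cross"`.
#' @param lambda_coef ascending polynomial coefficients of lambda(t) in um.
#' @return object of class `psoct_spectrometer`.
#' @export
spectrometer_model <- function(n_pixels = 2048,
                               channel = c("co", "cross"),
                               lambda_coef = NULL) {
  channel <- match.arg(channel)
  if (is.null(lambda_coef)) {
    lambda_coef <- if (channel == "co") c(0.7830, 0.1140, 0.0040)
                   else                 c(0.7836, 0.1230, -0.0066)
  }
  stopifnot(n_pixels >= 16)
  t <- seq(0, 1, length.out = n_pixels)
  lam <- polyval_asc(lambda_coef, t)
  if (any(diff(lam) <= 0))
    stop("pixel-to-wavelength mapping must be strictly increasing")
  structure(list(n_pixels = as.integer(n_pixels), channel = channel,
                 lambda_coef = lambda_coef),
            class = "psoct_spectrometer")
}

#' True pixel-to-wavenumber mapping of a spectrometer model
#' @param spectrometer a [spectrometer_model()].
#' @return wavenumber (rad/um) per pixel; strictly decreasing.
#' @export
spectrometer_wavenumbers <- function(spectrometer) {
  t <- seq(0, 1, length.out = spectrometer$n_pixels)
  2 * pi / polyval_asc(spectrometer$lambda_coef, t)
}

#' Maximum unambiguous (Nyquist) depth of a spectrometer sampling
#'
#' The largest optical-path depth whose fringe is sampled above two points
#' per period everywhere on the pixel grid: `pi / (2 * max|dk|)`.
#' @param spectrometer a [spectrometer_model()].
#' @export
nyquist_depth_um <- function(spectrometer) {
  k <- spectrometer_wavenumbers(spectrometer)
  pi / (2 * max(abs(diff(k))))
}

#' Layered corneal phantom description
#'
#' Five layers (epithelium, Bowman's layer, stroma, Descemet's membrane,
#' endothelium) with physical thicknesses in um, an interface amplitude
#' (square root of the relative co-polarized reflectivity) at each layer's
#' anterior boundary, and a cross-polarized fraction per layer. Only the
#' stroma carries a volumetric scatterer texture; the epithelium does not
#' alter the polarization state, so its cross fraction is fixed at zero.
#'
#' Texture statistics: the cross-polarized stromal texture is modeled as
#' sparse bright structures on a dark background — a Gaussian-filtered
#' white-noise field of which only the upper tail scatters. Three
#' quantities vary with fractional stromal depth `u`: the lateral
#' correlation length (structure size) grows as
#' `corr_len_range[1] + diff(corr_len_range) * u^corr_len_power` (um);
#' the structure density falls (the zeroed quantile rises linearly across
#' `texture_sparsity_range`); and the texture amplitude decays as
#' `texture_amplitude * exp(-log(texture_amplitude_drop) * u)`. Together
#' these emulate fine, dense structures anteriorly that evolve into
#' larger, sparser connected patterns posteriorly, with a slight decrease
#' of overall intensity with depth.
#'
#' @param thickness_um named physical thicknesses (um).
#' @param co_reflectivity relative co-channel reflectivity of each layer's
#'   anterior interface (the air/epithelium interface is the strong
#'   specular surface).
#' @param cross_fraction fraction of each layer's volumetric backscatter
#'   appearing in the cross-polarized channel, in `[0, 1]`.
#' @param refractive_index tissue refractive index (default 1.385).
#' @param posterior_reflectivity endothelium/aqueous interface reflectivity.
#' @param surface_depth_um optical depth of the anterior surface below the
#'   zero-delay line (near-constant under conical scanning).
#' @param surface_ripple_um amplitude of a slow lateral surface modulation.
#' @param surface_jitter_um standard deviation of per-A-scan sub-pixel
#'   surface roughness (um). Far below the axial resolution, it only
#'   decorrelates the fringe phase between A-scans, as real surface
#'   micro-roughness and speckle do, so that mean-spectrum subtraction
#'   removes the static pattern but not the (laterally varying) signal.
#' @param texture_amplitude anterior stromal texture amplitude (relative).
#' @param texture_amplitude_drop factor by which the amplitude decays from
#'   anterior to posterior stroma.
#' @param corr_len_range lateral correlation length (um) at the anterior
#'   and posterior ends of the stroma.
#' @param corr_len_power exponent shaping the growth with depth.
#' @param texture_sparsity_range quantile of the Gaussian field below
#'   which scatterers are zeroed, at the anterior and posterior ends of
#'   the stroma; higher = sparser structures.
#' @param sheet_spacing_um physical spacing of the texture sheets that
#'   discretise the stromal volume.
#' @return object of class `psoct_phantom`.
#' @export
phantom_spec <- function(thickness_um = c(epithelium = 48, bowman = 15,
                                          stroma = 450, descemet = 10,
                                          endothelium = 5),
                         co_reflectivity = c(epithelium = 1.0, bowman = 2.5e-3,
                                             stroma = 1.6e-3, descemet = 1e-3,
                                             endothelium = 4e-3),
                         cross_fraction = c(epithelium = 0, bowman = 0.1,
                                            stroma = 0.5, descemet = 0.2,
                                            endothelium = 0),
                         refractive_index = 1.385,
                         posterior_reflectivity = 6e-3,
                         surface_depth_um = 300,
                         surface_ripple_um = 5,
                         surface_jitter_um = 0.3,
                         texture_amplitude = 0.035,
                         texture_amplitude_drop = 2.5,
                         corr_len_range = c(15, 120),
                         corr_len_power = 2,
                         texture_sparsity_range = c(0.80, 0.92),
                         sheet_spacing_um = 12) {
  stopifnot(all(thickness_um > 0), all(co_reflectivity >= 0),
            all(cross_fraction >= 0 & cross_fraction <= 1),
            refractive_index >= 1, surface_depth_um > 0,
            length(corr_len_range) == 2, all(corr_len_range > 0),
            all(texture_sparsity_range >= 0 & texture_sparsity_range < 1),
            sheet_spacing_um > 0)
  if (cross_fraction[["epithelium"]] != 0)
    stop("the epithelium does not alter the polarization state; cross_fraction must be 0")
  structure(list(thickness_um = thickness_um,
                 co_reflectivity = co_reflectivity,
                 cross_fraction = cross_fraction,
                 refractive_index = refractive_index,
                 posterior_reflectivity = posterior_reflectivity,
                 surface_depth_um = surface_depth_um,
                 surface_ripple_um = surface_ripple_um,
                 surface_jitter_um = surface_jitter_um,
                 texture_amplitude = texture_amplitude,
                 texture_amplitude_drop = texture_amplitude_drop,
                 corr_len_range = corr_len_range,
                 corr_len_power = corr_len_power,
                 texture_sparsity_range = texture_sparsity_range,
                 sheet_spacing_um = sheet_spacing_um),
            class = "psoct_phantom")
}

#' Correlation length of the stromal texture at fractional depth u
#' @param spec a [phantom_spec()].
#' @param u fractional stromal depth in `[0, 1]`.
#' @return lateral correlation length in um.
#' @export
texture_corr_length_um <- function(spec, u) {
  spec$corr_len_range[1] +
    diff(spec$corr_len_range) * pmin(pmax(u, 0), 1)^spec$corr_len_power
}

#' Texture amplitude at fractional stromal depth u
#' @inheritParams texture_corr_length_um
#' @export
texture_amplitude_at <- function(spec, u) {
  spec$texture_amplitude *
    exp(-log(spec$texture_amplitude_drop) * pmin(pmax(u, 0), 1))
}

#' Texture sparsity (zeroed quantile) at fractional stromal depth u
#' @inheritParams texture_corr_length_um
#' @export
texture_sparsity_at <- function(spec, u) {
  spec$texture_sparsity_range[1] +
    diff(spec$texture_sparsity_range) * pmin(pmax(u, 0), 1)
}

#' Scan-position dependent dispersion ground truth
#'
#' The second-order (group-velocity) dispersion coefficient `a2` varies
#' smoothly with A-scan position as a polynomial in the centered scan
#' coordinate `t in [-1, 1]` (ascending coefficients `a2_coef`), emulating
#' the scan-angle dependent glass path of a conical scan through an
#' aspheric condenser lens. Units of `a2`: rad/(rad/um)^2, i.e. phase per
#' squared wavenumber deviation from `k0`. The third-order coefficient
#' defaults to zero.
#'
#' @param a2_coef ascending polynomial coefficients of a2(t).
#' @param a3 third-order coefficient, rad/(rad/um)^3.
#' @return object of class `psoct_dispersion_truth`.
#' @export
dispersion_truth <- function(a2_coef = c(2, 0, 16, 3), a3 = 0) {
  if (length(a2_coef) > 6L)
    stop("a2 profile must be a polynomial of order <= 5 in the scan coordinate")
  structure(list(a2_coef = a2_coef, a3 = a3),
            class = "psoct_dispersion_truth")
}

#' Evaluate the ground-truth a2 profile at each A-scan position
#' @param truth a [dispersion_truth()].
#' @param n_ascans number of A-scans in the B-scan.
#' @return numeric vector of a2 per A-scan.
#' @export
dispersion_truth_profile <- function(truth, n_ascans) {
  t <- seq(-1, 1, length.out = n_ascans)
  polyval_asc(truth$a2_coef, t)
}

#' Simulate one raw spectral interferogram
#'
#' Standard Fourier-domain OCT forward model on the spectrometer's native
#' (nonlinear-in-k) pixel grid:
#' `I(p) = S(k_p) * (dc_level + sum_j 2 a_j cos(2 k_p z_j +
#'   a2 (k_p - k0)^2 + a3 (k_p - k0)^3)) + fixed_pattern(p) + noise`.
#' Sample-sample interference (autocorrelation terms) is omitted under the
#' weak-scatterer approximation.
#'
#' @param reflectors data.frame with columns `depth_um` (optical path) and
#'   `amplitude` (square root of reflectivity; may be signed).
#' @param source a [source_spectrum()].
#' @param spectrometer a [spectrometer_model()].
#' @param dispersion numeric `c(a2, a3)` applied as sample dispersion.
#' @param dc_level reference (DC) level multiplying the envelope.
#' @param fixed_pattern optional static spectral vector added as-is.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param k0 center wavenumber for the dispersion expansion; defaults to
#'   the source's `k0`.
#' @return numeric vector of length `spectrometer$n_pixels`.
#' @export
simulate_fringe <- function(reflectors, source, spectrometer,
                            dispersion = c(0, 0), dc_level = 1,
                            fixed_pattern = NULL, noise_sigma = 0,
                            k0 = source$k0) {
  stopifnot(is.data.frame(reflectors),
            all(c("depth_um", "amplitude") %in% names(reflectors)))
  z_max <- nyquist_depth_um(spectrometer)
  bad <- reflectors$depth_um <= 0 | reflectors$depth_um >= z_max
  if (any(bad))
    stop(sprintf("reflector depth outside unambiguous range (0, %.1f um): %s",
                 z_max, paste(format(reflectors$depth_um[bad]), collapse = ", ")))
  k <- spectrometer_wavenumbers(spectrometer)
  env <- source_envelope(source, k)
  fringe <- rep(dc_level, spectrometer$n_pixels)
  dk0 <- k - k0
  disp_phase <- dispersion[1] * dk0^2 +
    (if (length(dispersion) > 1) dispersion[2] else 0) * dk0^3
  for (j in seq_len(nrow(reflectors))) {
    fringe <- fringe + 2 * reflectors$amplitude[j] *
      cos(2 * k * reflectors$depth_um[j] + disp_phase)
  }
  out <- env * fringe
  if (!is.null(fixed_pattern)) {
    stopifnot(length(fixed_pattern) == length(out))
    out <- out + fixed_pattern
  }
  if (noise_sigma > 0) out <- out + stats::rnorm(length(out), 0, noise_sigma)
  out
}

#' Simulate auxiliary-interferometer calibration fringes
#'
#' A bulk-optics Michelson with both arms terminated by mirrors produces a
#' single-frequency-in-k fringe `S(k) cos(2 k z)` that each spectrometer
#' samples on its own nonlinear pixel grid. These fringes are the input to
#' [derive_mapping()].
#'
#' @param spectrometers list of [spectrometer_model()]s (one per channel).
#' @param mirror_delay_um single-pass arm-length difference (optical, um).
#' @param source a [source_spectrum()].
#' @return named list of fringe vectors, one per channel.
#' @export
simulate_calibration_fringes <- function(spectrometers, mirror_delay_um,
                                         source = source_spectrum()) {
  stopifnot(mirror_delay_um > 0)
  lapply(spectrometers, function(sp) {
    if (mirror_delay_um >= nyquist_depth_um(sp))
      stop("mirror delay beyond the unambiguous range of the spectrometer")
    k <- spectrometer_wavenumbers(sp)
    source_envelope(source, k) * cos(2 * k * mirror_delay_um)
  })
}

# Gaussian-correlated random field on an nx x ny grid with lateral
# correlation length ell_px (pixels): white noise convolved with a
# Gaussian kernel of sigma = ell_px / 2 on the torus (circular FFT
# convolution, exactly stationary), re-standardised to zero mean and
# unit sd. The field's autocorrelation is Gaussian with standard
# deviation ell_px / sqrt(2).
gaussian_random_field <- function(nx, ny, ell_px) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  if (ell_px > 0.5) {
    sg <- ell_px / 2
    dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
    dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
    kern <- exp(-dx^2 / (2 * sg^2)) %o% exp(-dy^2 / (2 * sg^2))
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (nx * ny)
  }
  if (stats::sd(z) == 0) return(matrix(0, nx, ny))
  (z - mean(z)) / stats::sd(z)
}

# Sparse scatterer field: keep the upper tail of a Gaussian-correlated
# field above its `sparsity` quantile (shifted so the background is
# exactly zero), re-normalised to unit sd. Structures are connected
# suprathreshold regions whose size scales with ell_px.
texture_field <- function(nx, ny, ell_px, sparsity = 0.85) {
  f <- gaussian_random_field(nx, ny, ell_px)
  g <- pmax(f - stats::quantile(f, sparsity), 0)
  s <- stats::sd(g)
  if (s == 0) return(g)
  g / s
}

#' Synthesize a flattened stromal texture volume directly
#'
#' Generates the cross-polarized en-face texture stack of the phantom
#' stroma without going through fringe encoding and reconstruction: plane
#' `i` at fractional stromal depth `u` holds the intensity
#' `(A(u) field_u + noise)^2`, where `field_u` is a unit-variance
#' Gaussian-correlated random field with lateral correlation length
#' `texture_corr_length_um(spec, u)` and `A(u) =
#' texture_amplitude_at(spec, u)`. Optionally appends signal-free
#' (noise-only) planes emulating depths beyond the sample, which the
#' automatic IACF threshold uses as its noise reference. This is the
#' desk-scale oracle for the IACF chain: the texture statistics are known
#' exactly, with none of the axial blurring of the full forward model.
#'
#' @param spec a [phantom_spec()].
#' @param nx,ny lateral image size in pixels.
#' @param pitch_um lateral pixel pitch (um).
#' @param n_planes number of stromal depth planes.
#' @param n_noise_planes signal-free planes appended below the stroma.
#' @param noise_sigma additive amplitude-noise standard deviation.
#' @param amplitude_fun,length_fun,sparsity_fun optional overrides `f(u)`
#'   for the texture amplitude, correlation length (um) and sparsity
#'   (zeroed quantile) at fractional depth u.
#' @param seed integer seed.
#' @return array `(n_planes + n_noise_planes, nx, ny)` of intensities,
#'   with attributes `u` (fractional depth per plane) and `pitch_um`.
#' @export
texture_volume <- function(spec = phantom_spec(), nx = 384, ny = 384,
                           pitch_um = 11, n_planes = 20,
                           n_noise_planes = 3, noise_sigma = 0.002,
                           amplitude_fun = NULL, length_fun = NULL,
                           sparsity_fun = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(amplitude_fun))
    amplitude_fun <- function(u) texture_amplitude_at(spec, u)
  if (is.null(length_fun))
    length_fun <- function(u) texture_corr_length_um(spec, u)
  if (is.null(sparsity_fun))
    sparsity_fun <- function(u) texture_sparsity_at(spec, u)
  u <- (seq_len(n_planes) - 0.5) / n_planes
  vol <- array(0, dim = c(n_planes + n_noise_planes, nx, ny))
  for (i in seq_len(n_planes)) {
    f <- texture_field(nx, ny, length_fun(u[i]) / pitch_um,
                       sparsity_fun(u[i]))
    vol[i, , ] <- (amplitude_fun(u[i]) * f +
                     matrix(stats::rnorm(nx * ny, 0, noise_sigma), nx, ny))^2
  }
  for (i in seq_len(n_noise_planes)) {
    vol[n_planes + i, , ] <-
      matrix(stats::rnorm(nx * ny, 0, noise_sigma), nx, ny)^2
  }
  attr(vol, "u") <- u
  attr(vol, "pitch_um") <- pitch_um
  vol
}

#' Simulate a raw PS-OCT volume of the corneal phantom
#'
#' Assembles raw spectral fringes for both polarization channels of a
#' layered corneal phantom under a conical scan. Co-polarized signal:
#' layer interfaces plus the polarization-preserving share of the stromal
#' texture. Cross-polarized signal: the cross-polarized share of each
#' layer's volumetric texture (zero for the epithelium). The whole
#' reflector stack shifts per A-scan with the surface profile and per
#' B-scan with axial motion; the dispersion coefficient varies per A-scan
#' according to `truth`.
#'
#' @param spec a [phantom_spec()].
#' @param truth a [dispersion_truth()].
#' @param geometry list with `n_bscans`, `n_ascans`, `fov_mm` (defaults
#'   256, 1024, 11) and optional `bm_mode` (logical; repeat the same
#'   lateral line for every B-scan, y-scanner held).
#' @param source a [source_spectrum()].
#' @param spectrometers named list with `co` and `cross`
#'   [spectrometer_model()]s (equal `n_pixels`).
#' @param noise list with `dc_level`, `fixed_pattern_sd` (per-B-scan static
#'   spectral pattern), `sigma` (per-pixel Gaussian noise sd).
#' @param motion_um per-B-scan axial displacement (um); a numeric vector
#'   recycled to `n_bscans`, or `NULL` for a smooth default sinusoid of
#'   15 um amplitude emulating slow axial eye drift.
#' @param seed integer seed; the volume is bit-identical for equal seeds.
#' @return object of class `psoct_raw_volume`: arrays `co`, `cross` of dim
#'   `(n_bscans, n_ascans, n_pixels)` plus `truth` (surface map um, a2 per
#'   A-scan, motion, texture sheets) and the acquisition metadata.
#' @export
simulate_volume <- function(spec = phantom_spec(),
                            truth = dispersion_truth(),
                            geometry = list(),
                            source = source_spectrum(),
                            spectrometers = list(
                              co = spectrometer_model(channel = "co"),
                              cross = spectrometer_model(channel = "cross")),
                            noise = list(dc_level = 1, fixed_pattern_sd = 0.05,
                                         sigma = 0.002),
                            motion_um = NULL,
                            seed = 1L) {
  geom <- utils::modifyList(list(n_bscans = 256L, n_ascans = 1024L,
                                 fov_mm = 11, bm_mode = FALSE), geometry)
  stopifnot(geom$n_bscans >= 1, geom$n_ascans >= 8, geom$fov_mm > 0)
  nb <- as.integer(geom$n_bscans); na <- as.integer(geom$n_ascans)
  np <- spectrometers$co$n_pixels
  stopifnot(np == spectrometers$cross$n_pixels)
  set.seed(seed)

  nidx <- spec$refractive_index
  pitch_um <- geom$fov_mm * 1000 / na

  # reflector stack at zero surface offset: optical depths below surface
  th <- spec$thickness_um
  iface_phys <- cumsum(c(0, th[c("epithelium", "bowman", "stroma",
                                 "descemet")]))
  iface_opt <- nidx * iface_phys
  iface_amp <- sqrt(spec$co_reflectivity[c("epithelium", "bowman", "stroma",
                                           "descemet", "endothelium")])
  post_opt <- nidx * sum(th)
  # stromal texture sheets
  stroma_top_phys <- sum(th[c("epithelium", "bowman")])
  n_sheets <- max(3L, floor(th[["stroma"]] / spec$sheet_spacing_um))
  sheet_phys <- stroma_top_phys +
    (seq_len(n_sheets) - 0.5) / n_sheets * th[["stroma"]]
  sheet_u <- (sheet_phys - stroma_top_phys) / th[["stroma"]]
  sheet_opt <- nidx * sheet_phys
  sheet_len_um <- texture_corr_length_um(spec, sheet_u)
  sheet_amp <- texture_amplitude_at(spec, sheet_u)
  sheet_sparsity <- texture_sparsity_at(spec, sheet_u)

  ny_field <- if (geom$bm_mode) 1L else nb
  sheet_fields <- lapply(seq_len(n_sheets), function(s)
    texture_field(na, ny_field, sheet_len_um[s] / pitch_um,
                  sheet_sparsity[s]))

  # surface geometry: near-constant depth with a slow lateral ripple
  xs <- seq(-1, 1, length.out = na)
  ys <- if (geom$bm_mode) rep(0, nb) else seq(-1, 1, length.out = nb)
  if (is.null(motion_um)) {
    motion_um <- 15 * sin(2 * pi * seq_len(nb) / max(nb, 2) * 1.7)
  } else {
    motion_um <- rep_len(motion_um, nb)
  }
  surface_um <- matrix(0, nb, na)
  for (b in seq_len(nb)) {
    surface_um[b, ] <- spec$surface_depth_um +
      spec$surface_ripple_um * cos(pi * xs / 2) * cos(pi * ys[b] / 2) +
      motion_um[b] +
      stats::rnorm(na, 0, spec$surface_jitter_um)
  }

  a2_true <- dispersion_truth_profile(truth, na)
  cf <- spec$cross_fraction[["stroma"]]

  # per-channel static reflector matrices (depths at zero surface offset)
  base_depths <- c(iface_opt, post_opt, sheet_opt)
  n_iface <- length(iface_opt) + 1L
  vols <- list()
  fp <- list(co = NULL, cross = NULL)
  for (ch in c("co", "cross")) {
    sp <- spectrometers[[ch]]
    k <- spectrometer_wavenumbers(sp)
    z_nyq <- pi / (2 * max(abs(diff(k))))
    if (max(base_depths) + max(surface_um) >= z_nyq)
      stop(sprintf("phantom extends beyond the unambiguous depth range (%.0f um)",
                   z_nyq))
    env <- source_envelope(source, k)
    dk0 <- k - source$k0
    C <- cos(2 * outer(k, base_depths))
    S <- sin(2 * outer(k, base_depths))
    # amplitudes: interfaces only in co; sheets split by cross fraction
    amp_iface <- if (ch == "co") c(iface_amp, sqrt(spec$posterior_reflectivity))
                 else rep(0, n_iface)
    sheet_scale <- if (ch == "co") (1 - cf) else cf
    fp[[ch]] <- stats::rnorm(np, 0, noise$fixed_pattern_sd)
    vol <- array(0, dim = c(nb, na, np))
    for (b in seq_len(nb)) {
      fb <- if (geom$bm_mode) 1L else b
      A <- rbind(matrix(amp_iface, n_iface, na),
                 vapply(seq_len(na), function(x)
                   sheet_amp * sheet_scale *
                     vapply(sheet_fields, function(f) f[x, fb], 0),
                   numeric(n_sheets)))
      M1 <- C %*% A
      M2 <- S %*% A
      theta <- outer(2 * k, surface_um[b, ]) +
        outer(dk0^2, a2_true) + truth$a3 * matrix(dk0^3, np, na)
      F <- cos(theta) * M1 - sin(theta) * M2
      bsc <- env * (noise$dc_level + 2 * F) + fp[[ch]]
      if (noise$sigma > 0)
        bsc <- bsc + matrix(stats::rnorm(np * na, 0, noise$sigma), np, na)
      vol[b, , ] <- t(bsc)
    }
    vols[[ch]] <- vol
  }

  structure(list(
    co = vols$co, cross = vols$cross,
    geometry = geom, source = source, spectrometers = spectrometers,
    noise = noise, seed = seed, pitch_um = pitch_um,
    truth = list(surface_um = surface_um, a2 = a2_true, a3 = truth$a3,
                 motion_um = motion_um,
                 sheets = list(depth_phys_um = sheet_phys,
                               depth_opt_um = sheet_opt,
                               u = sheet_u, corr_len_um = sheet_len_um,
                               amplitude = sheet_amp, fields = sheet_fields),
                 interfaces_opt_um = c(iface_opt, post_opt),
                 fixed_pattern = fp)),
    class = "psoct_raw_volume")
}

#' @export
print.psoct_raw_volume <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("PS-OCT raw volume: %d B-scans x %d A-scans x %d pixels%s\n",
              g$n_bscans, g$n_ascans, x$spectrometers$co$n_pixels,
              if (isTRUE(g$bm_mode)) " (B-M mode)" else ""))
  cat(sprintf("  lateral pitch %.1f um, seed %d\n", x$pitch_um, x$seed))
  invisible(x)
}
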