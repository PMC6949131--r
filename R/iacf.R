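#' IACF analysis configuration
#'
#' Parameters of the integrated autocorrelation factor computed on
#' cross-polarized en-face images: intensity threshold, circular region of
#' interest, and central integration window of the autocorrelation map.
#'
#' @param threshold intensity threshold; values below it are zeroed before
#'   the autocorrelation. `NULL` (default) lets [iacf_depth_profile()]
#'   derive it as the `noise_quantile` quantile of the intensity of a
#'   signal-free deep plane, so that only a few isolated noise pixels
#'   survive where no signal is expected.
#' @param noise_quantile quantile of the signal-free reference plane used
#'   for the automatic threshold (default 0.995: ~0.5 percent of pure
#'   noise pixels survive).
#' @param roi_diameter_mm diameter of the circular analysis region
#'   (default 4.2 mm, the central cornea).
#' @param pixel_pitch_um lateral pixel pitch (default 11 um/pixel).
#' @param integration_halfwidth half-width (pixels) of the square central
#'   lag window that is summed; default 30, i.e. a 61 x 61 window spanning
#'   the central ~60 pixels of the autocorrelation function.
#' @return object of class `psoct_iacf_config`.
#' @export
iacf_config <- function(threshold = NULL, noise_quantile = 0.995,
                        roi_diameter_mm = 4.2, pixel_pitch_um = 11,
                        integration_halfwidth = 30) {
  stopifnot(is.null(threshold) || threshold >= 0,
            noise_quantile > 0, noise_quantile < 1,
            roi_diameter_mm > 0, pixel_pitch_um > 0,
            integration_halfwidth >= 1)
  structure(list(threshold = threshold, noise_quantile = noise_quantile,
                 roi_diameter_mm = roi_diameter_mm,
                 pixel_pitch_um = pixel_pitch_um,
                 integration_halfwidth = as.integer(integration_halfwidth)),
            class = "psoct_iacf_config")
}

#' Zero image values below a threshold
#'
#' Minimises the influence of noise on the autocorrelation: all values
#' below `threshold` are set to zero, values at or above it are unchanged.
#'
#' @param image numeric matrix.
#' @param threshold non-negative scalar.
#' @export
threshold_image <- function(image, threshold) {
  stopifnot(threshold >= 0)
  image[image < threshold] <- 0
  image
}

#' Circular region-of-interest mask
#'
#' Logical mask of the centered circle of the given diameter; pixels whose
#' center is within the radius belong to the ROI.
#' @param nx,ny image dimensions (pixels).
#' @param diameter_px ROI diameter in pixels.
#' @export
circular_roi_mask <- function(nx, ny, diameter_px) {
  if (diameter_px > min(nx, ny))
    stop("ROI does not fit in the image")
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  outer(seq_len(nx), seq_len(ny),
        function(i, j) (i - cx)^2 + (j - cy)^2 <= (diameter_px / 2)^2)
}

#' Normalized, center-eliminated 2D autocorrelation
#'
#' Raw (non-mean-subtracted) 2D autocorrelation of the masked image over
#' non-circular (zero-padded) lags, computed by FFT, normalised by its
#' zero-lag value, after which the central (zero-lag) point is set to
#' zero to remove its exceedingly high contribution. The map is symmetric
#' under lag negation.
#'
#' @param image numeric matrix (already thresholded; pixels outside the
#'   ROI should be zero, see [circular_roi_mask()]).
#' @return matrix of dimension `(2*nx-1, 2*ny-1)` with zero lag at the
#'   center; attributes `lag_x`, `lag_y` give the lag axes in pixels.
#' @export
normalized_autocorrelation <- function(image) {
  stopifnot(is.matrix(image))
  if (all(image == 0)) stop("all-zero image: normalization undefined")
  nx <- nrow(image); ny <- ncol(image)
  px <- stats::nextn(2L * nx - 1L, 2)
  py <- stats::nextn(2L * ny - 1L, 2)
  Z <- matrix(0, px, py)
  Z[seq_len(nx), seq_len(ny)] <- image
  FZ <- stats::fft(Z)
  C <- Re(stats::fft(FZ * Conj(FZ), inverse = TRUE)) / (px * py)
  # reorder lags to -(n-1)..(n-1) with zero lag centered
  ix <- c(px - ((nx - 1L):1L) + 1L, 1L:nx)
  iy <- c(py - ((ny - 1L):1L) + 1L, 1L:ny)
  M <- C[ix, iy]
  M <- M / M[nx, ny]
  M[nx, ny] <- 0
  attr(M, "lag_x") <- -(nx - 1L):(nx - 1L)
  attr(M, "lag_y") <- -(ny - 1L):(ny - 1L)
  M
}

#' Integrated autocorrelation factor of a correlation map
#'
#' Sum of the normalized, center-eliminated autocorrelation over the
#' square central window of lags `|dx| <= w`, `|dy| <= w`. A proxy for
#' the size of connected texture features: larger, more connected
#' structures put more correlation mass near the origin.
#'
#' @param corr_map a [normalized_autocorrelation()] result.
#' @param integration_halfwidth window half-width `w` in pixels.
#' @return scalar IACF (dimensionless, non-negative for typical inputs).
#' @export
iacf <- function(corr_map, integration_halfwidth = 30) {
  w <- as.integer(integration_halfwidth)
  cx <- (nrow(corr_map) + 1L) %/% 2L
  cy <- (ncol(corr_map) + 1L) %/% 2L
  if (cx - w < 1L || cy - w < 1L ||
      cx + w > nrow(corr_map) || cy + w > ncol(corr_map))
    stop("integration window larger than the correlation map")
  sum(corr_map[(cx - w):(cx + w), (cy - w):(cy + w)])
}

#' IACF of a single en-face image
#'
#' Convenience wrapper: threshold, apply the circular ROI, autocorrelate,
#' integrate. Returns 0 (with the all-zero flag) when no pixel survives
#' the threshold, which is the natural limit for signal-free planes.
#'
#' @param image en-face matrix `(ascan, bscan)`.
#' @param config an [iacf_config()] with a non-`NULL` threshold.
#' @return list: `iacf`, `integrated_intensity` (sum of the unthresholded
#'   image over the ROI), `n_above_threshold`, `all_zero`.
#' @export
iacf_of_image <- function(image, config) {
  stopifnot(inherits(config, "psoct_iacf_config"),
            !is.null(config$threshold))
  d_px <- config$roi_diameter_mm * 1000 / config$pixel_pitch_um
  mask <- circular_roi_mask(nrow(image), ncol(image), d_px)
  roi <- image
  roi[!mask] <- 0
  ii <- sum(roi)
  thr <- threshold_image(roi, config$threshold)
  if (all(thr == 0))
    return(list(iacf = 0, integrated_intensity = ii,
                n_above_threshold = 0L, all_zero = TRUE))
  M <- normalized_autocorrelation(thr)
  list(iacf = iacf(M, config$integration_halfwidth),
       integrated_intensity = ii,
       n_above_threshold = sum(thr > 0), all_zero = FALSE)
}

#' Depth profile of the integrated autocorrelation factor
#'
#' For every depth plane below the flattening reference: threshold, ROI,
#' normalized center-eliminated autocorrelation, IACF — plus the
#' integrated intensity of the ROI as a control curve that separates
#' texture-size changes from plain signal changes. When no explicit
#' threshold is configured it is set to the `noise_quantile` quantile of
#' the ROI intensity of the `noise_depth` plane (a signal-free deep
#' plane), leaving only a few visible noise pixels where no signal is
#' expected.
#'
#' @param flat a [flatten_volume()] result (cross-polarized channel), or
#'   a bare `(depth, ascan, bscan)` array.
#' @param config an [iacf_config()].
#' @param depths depth-below-surface pixels to evaluate; default every
#'   plane from 0 to the deepest full row.
#' @param noise_depth depth (pixels below surface) of a signal-free plane
#'   used for the automatic threshold; default the deepest evaluated
#'   plane.
#' @param axial_pitch_um_tissue axial pixel pitch in tissue (um/pixel) for
#'   the um depth axis; optional.
#' @return object of class `psoct_iacf_profile`: data.frame with
#'   `depth_px`, `depth_um`, `iacf`, `integrated_intensity`,
#'   `n_above_threshold`; plus the `threshold` used.
#' @export
iacf_depth_profile <- function(flat, config = iacf_config(), depths = NULL,
                               noise_depth = NULL,
                               axial_pitch_um_tissue = NA_real_) {
  vol <- if (inherits(flat, "psoct_flat")) flat$volume else flat
  ref <- if (inherits(flat, "psoct_flat")) flat$reference_row else 1L
  nz <- dim(vol)[1]
  if (is.null(depths)) depths <- 0:(nz - ref)
  if (is.null(noise_depth)) noise_depth <- max(depths)
  cfg <- config
  if (is.null(cfg$threshold)) {
    plane <- enface_slice(flat, noise_depth)
    d_px <- cfg$roi_diameter_mm * 1000 / cfg$pixel_pitch_um
    mask <- circular_roi_mask(nrow(plane), ncol(plane), d_px)
    cfg$threshold <- stats::quantile(plane[mask], cfg$noise_quantile,
                                     names = FALSE)
  }
  rows <- lapply(depths, function(d) {
    r <- iacf_of_image(enface_slice(flat, d), cfg)
    data.frame(depth_px = d, depth_um = d * axial_pitch_um_tissue,
               iacf = r$iacf, integrated_intensity = r$integrated_intensity,
               n_above_threshold = r$n_above_threshold)
  })
  structure(list(profile = do.call(rbind, rows), threshold = cfg$threshold,
                 config = cfg),
            class = "psoct_iacf_profile")
}

#' @export
print.psoct_iacf_profile <- function(x, ...) {
  cat(sprintf("IACF depth profile: %d planes, threshold %.3g\n",
              nrow(x$profile), x$threshold))
  print(utils::head(x$profile), ...)
  invisible(x)
}
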