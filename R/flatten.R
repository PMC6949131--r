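#' Detect the corneal surface in one A-scan
#'
#' Returns the shallowest local maximum (3-pixel neighborhood) whose
#' height is at least `min_prominence_fraction` times the A-scan maximum,
#' searching below the DC-adjacent exclusion region. The first peak above
#' threshold wins even if a deeper peak is higher, so the anterior surface
#' is preferred over stronger posterior reflexes. Returns `NA` (invalid)
#' if no qualifying peak exists.
#'
#' @param ascan intensity A-scan (depth profile).
#' @param min_prominence_fraction fraction of the A-scan maximum a peak
#'   must reach (default 0.3).
#' @param dc_exclusion depth pixels skipped at the top of the A-scan.
#' @param min_snr the A-scan maximum must exceed `min_snr` times the
#'   A-scan median, otherwise the A-scan is considered signal-free and
#'   flagged invalid (the maximum of pure noise sits around 10x its
#'   median, a genuine surface reflex orders of magnitude higher).
#' @return integer surface depth index (1-based), or `NA_integer_`.
#' @export
detect_surface <- function(ascan, min_prominence_fraction = 0.3,
                           dc_exclusion = 20, min_snr = 20) {
  n <- length(ascan)
  lo <- max(2L, dc_exclusion + 1L)
  if (lo >= n - 1L) return(NA_integer_)
  seg <- lo:(n - 1L)
  mx <- max(ascan[seg])
  if (mx <= min_snr * stats::median(ascan[seg])) return(NA_integer_)
  thr <- min_prominence_fraction * mx
  is_peak <- ascan[seg] >= ascan[seg - 1L] & ascan[seg] >= ascan[seg + 1L] &
    ascan[seg] >= thr
  hits <- seg[is_peak]
  if (length(hits) == 0L) return(NA_integer_)
  hits[1L]
}

#' Detect the surface map of a reconstructed volume
#'
#' Applies [detect_surface()] to every A-scan of an intensity volume.
#'
#' @param volume intensity array `(depth, ascan, bscan)`.
#' @param ... passed to [detect_surface()].
#' @return object of class `psoct_surface`: integer matrix `index`
#'   `(ascan, bscan)` with `NA` where detection failed, and `valid`.
#' @export
detect_surface_map <- function(volume, ...) {
  stopifnot(length(dim(volume)) == 3)
  idx <- apply(volume, c(2, 3), detect_surface, ...)
  structure(list(index = idx, valid = !is.na(idx)), class = "psoct_surface")
}

#' Flatten a volume to its detected surface
#'
#' Shifts every A-scan by an integer number of pixels so its surface sits
#' at a common reference row, which also removes per-B-scan axial motion.
#' Invalid A-scans (failed detection) are filled with the nearest valid
#' surface index along the fast axis; if more than `max_invalid_fraction`
#' of A-scans are invalid the operation aborts. Rows shifted in from
#' outside the recorded range are zero-filled.
#'
#' @param volume intensity array `(depth, ascan, bscan)`.
#' @param surface a [detect_surface_map()] result (or integer matrix).
#' @param reference_row row at which the surface is placed; default the
#'   median detected surface index.
#' @param max_invalid_fraction maximum tolerated fraction of invalid
#'   A-scans (default 0.1).
#' @return list of class `psoct_flat`: `volume` (flattened), `shift`
#'   matrix, `reference_row`, `surface`.
#' @export
flatten_volume <- function(volume, surface, reference_row = NULL,
                           max_invalid_fraction = 0.1) {
  stopifnot(length(dim(volume)) == 3)
  idx <- if (inherits(surface, "psoct_surface")) surface$index else surface
  stopifnot(all(dim(idx) == dim(volume)[2:3]))
  n_invalid <- sum(is.na(idx))
  if (n_invalid > max_invalid_fraction * length(idx))
    stop(sprintf("surface invalid for %d of %d A-scans", n_invalid,
                 length(idx)))
  # nearest-neighbor fill along the fast axis
  for (b in seq_len(ncol(idx))) {
    col <- idx[, b]
    if (anyNA(col)) {
      ok <- which(!is.na(col))
      if (length(ok) == 0L) stop("B-scan ", b, " has no valid surface")
      bad <- which(is.na(col))
      col[bad] <- col[ok[vapply(bad, function(i)
        which.min(abs(ok - i)), 0L)]]
      idx[, b] <- col
    }
  }
  if (is.null(reference_row))
    reference_row <- as.integer(round(stats::median(idx)))
  nz <- dim(volume)[1]
  shift <- idx - reference_row   # positive: surface too deep, move up
  out <- array(0, dim = dim(volume))
  for (b in seq_len(dim(volume)[3])) {
    for (x in seq_len(dim(volume)[2])) {
      s <- shift[x, b]
      src <- (1L + max(s, 0L)):(nz + min(s, 0L))
      out[src - s, x, b] <- volume[src, x, b]
    }
  }
  structure(list(volume = out, shift = shift,
                 reference_row = reference_row, surface = idx),
            class = "psoct_flat")
}

#' Extract an en-face plane from a flattened volume
#'
#' Single-pixel-thick constant-depth plane at `depth_below_surface` pixels
#' below the flattening reference row; optionally averaged over a small
#' axial window.
#'
#' @param flat a [flatten_volume()] result (or a bare `(depth, ascan,
#'   bscan)` array, in which case the reference row is 1).
#' @param depth_below_surface depth below the reference row, pixels (>= 0).
#' @param window odd axial averaging window in pixels (default 1: single
#'   plane).
#' @return matrix `(ascan, bscan)`.
#' @export
enface_slice <- function(flat, depth_below_surface, window = 1) {
  vol <- if (inherits(flat, "psoct_flat")) flat$volume else flat
  ref <- if (inherits(flat, "psoct_flat")) flat$reference_row else 1L
  stopifnot(length(dim(vol)) == 3, depth_below_surface >= 0,
            window >= 1, window %% 2 == 1)
  row <- ref + as.integer(round(depth_below_surface))
  if (row < 1L || row > dim(vol)[1])
    stop(sprintf("depth %d below surface is outside the volume (rows 1..%d, reference %d)",
                 as.integer(depth_below_surface), dim(vol)[1], ref))
  if (window == 1) return(vol[row, , ])
  h <- (window - 1L) %/% 2L
  rows <- max(1L, row - h):min(dim(vol)[1], row + h)
  apply(vol[rows, , , drop = FALSE], c(2, 3), mean)
}

#' Average repeated B-scans (B-M-mode protocol)
#'
#' Arithmetic mean of aligned intensity B-scans recorded at the same
#' lateral position, increasing the signal-to-noise ratio approximately as
#' the square root of the frame count.
#'
#' @param flat a [flatten_volume()] result of a B-M-mode volume.
#' @param frames which B-scan indices to average (default all).
#' @return matrix `(depth, ascan)`.
#' @export
average_bscans <- function(flat, frames = NULL) {
  vol <- if (inherits(flat, "psoct_flat")) flat$volume else flat
  if (is.null(frames)) frames <- seq_len(dim(vol)[3])
  apply(vol[, , frames, drop = FALSE], c(1, 2), mean)
}
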