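#' Scan protocol of a repeated-B-scan SD-OCTA acquisition
#'
#' Describes the acquisition geometry: A-lines per B-scan along the fast axis,
#' slow-axis positions, repeated frames per position (the raster that turns a
#' structural volume into an angiographic one), axial depth samples after
#' reconstruction, and spectrometer pixels. The defaults mirror a
#' high-resolution small-animal protocol: 500 A-scans per B-scan, 400 slow
#' positions, 5 repeats per position (so 2000 B-scan frames per volume), and a
#' 2048-pixel line-scan spectrometer giving 1024 depth samples.
#'
#' @param n_alines_per_bscan A-lines per B-scan (fast axis).
#' @param n_positions slow-axis positions per volume.
#' @param n_repeats repeated frames per slow position; `n_repeats - 1`
#'   sequential pairs feed the complex-difference angiogram.
#' @param n_spectral spectrometer pixels per A-line.
#' @param n_depth axial samples after reconstruction; defaults to
#'   `n_spectral / 2` (the positive-frequency half-space).
#' @param pixel_size_xy_um,pixel_size_z_um lateral and axial micrometers per
#'   pixel.
#' @return an object of class `scan_protocol`.
#' @export
#' @examples
#' p <- scan_protocol()
#' n_frames(p)  # 2000 cross-sectional frames per volume
scan_protocol <- function(n_alines_per_bscan = 500L,
                          n_positions = 400L,
                          n_repeats = 5L,
                          n_spectral = 2048L,
                          n_depth = NULL,
                          pixel_size_xy_um = 5,
                          pixel_size_z_um = 2) {
  n_depth <- as.integer(n_depth %||% (n_spectral %/% 2L))
  p <- list(
    n_alines_per_bscan = as.integer(n_alines_per_bscan),
    n_positions = as.integer(n_positions),
    n_repeats = as.integer(n_repeats),
    n_spectral = as.integer(n_spectral),
    n_depth = n_depth,
    pixel_size_xy_um = pixel_size_xy_um,
    pixel_size_z_um = pixel_size_z_um
  )
  counts <- unlist(p[c("n_alines_per_bscan", "n_positions", "n_repeats",
                       "n_spectral", "n_depth")])
  if (any(counts < 1L)) {
    abort("all scan_protocol counts must be >= 1", class = "octapipe_config_error")
  }
  if (any(c(p$pixel_size_xy_um, p$pixel_size_z_um) <= 0)) {
    abort("pixel sizes must be positive", class = "octapipe_config_error")
  }
  structure(p, class = "scan_protocol")
}

#' Frame bookkeeping for a scan protocol
#'
#' `n_frames()` is the number of cross-sectional B-scan frames acquired per
#' volume (`n_positions * n_repeats`); `n_octa_bscans()` is the number of
#' angiographic B-scans that result (one per slow position).
#'
#' @param protocol a [scan_protocol()].
#' @return an integer count.
#' @export
n_frames <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$n_positions * protocol$n_repeats
}

#' @rdname n_frames
#' @export
n_octa_bscans <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  protocol$n_positions
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    "<scan_protocol> %d A-lines x %d positions x %d repeats; %d spectral px -> %d depth px\n",
    x$n_alines_per_bscan, x$n_positions, x$n_repeats, x$n_spectral, x$n_depth
  ))
  cat(sprintf("  pixel size: %.3g um (xy), %.3g um (z); %d frames/volume\n",
              x$pixel_size_xy_um, x$pixel_size_z_um, n_frames(x)))
  invisible(x)
}
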