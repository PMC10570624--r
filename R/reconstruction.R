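# SD-OCT reconstruction: k-space resampling, FFT to complex B-scans,
# log-scaled structural images, reflectance normalization and image quality.

#' Resample a spectral frame to a uniform wavenumber grid
#'
#' Interpolates each A-line's fringe from the calibrated (generally
#' non-uniform) wavenumber samples onto a uniform grid spanning the same
#' range, using cubic splines. Endpoints are preserved exactly; an already
#' linear-in-k calibration reproduces the input to numerical precision.
#'
#' @param frame real matrix `[n_spectral, n_alines]`, one fringe per column.
#' @param calibration a `spectral_calibration` for the frame's pixel axis.
#' @return a matrix of the same shape, uniformly sampled in wavenumber
#'   (increasing).
#' @export
resample_to_k <- function(frame, calibration) {
  if (anyNA(frame)) {
    abort("spectral frame contains NaN/NA", class = "octapipe_data_error")
  }
  k <- check_calibration(calibration, nrow(frame))
  if (k[1] > k[length(k)]) {  # make increasing
    k <- rev(k)
    frame <- frame[rev(seq_len(nrow(frame))), , drop = FALSE]
  }
  ku <- seq(k[1], k[length(k)], length.out = length(k))
  out <- frame
  for (j in seq_len(ncol(frame))) {
    out[, j] <- splinefun(k, frame[, j], method = "fmm")(ku)
  }
  out
}

#' Reconstruct a complex B-scan from a k-uniform spectral frame
#'
#' Per A-line: subtract the spectral mean (DC removal), apply the discrete
#' Fourier transform, and keep the positive-frequency half-space. Output
#' element `d + 1` corresponds to depth bin `d` (`d = 0` is the removed DC
#' bin), with amplitudes scaled so a fringe `2 A cos(2 pi d p / n_spectral +
#' phase)` reconstructs to magnitude `A` at bin `d`.
#'
#' @param frame real matrix `[n_spectral, n_alines]`, uniform in wavenumber.
#' @return complex matrix `[n_spectral / 2, n_alines]`.
#' @export
reconstruct_bscan <- function(frame) {
  ns <- nrow(frame)
  frame <- sweep(frame, 2, colMeans(frame))
  X <- mvfft(frame)
  X[seq_len(ns %/% 2), , drop = FALSE] / ns
}

#' Reconstruct a full spectral volume to a complex OCT volume
#'
#' Applies [resample_to_k()] then [reconstruct_bscan()] to every
#' (position, repeat) frame.
#'
#' @param svolume a `spectral_volume`.
#' @return an `oct_volume` with `n_depth = n_spectral / 2` depth bins.
#' @export
reconstruct_volume <- function(svolume) {
  stopifnot(inherits(svolume, "spectral_volume"))
  dm <- dim(svolume$frames)
  ns <- dm[1]
  nd <- ns %/% 2L
  out <- array(complex(real = 0, imaginary = 0), dim = c(nd, dm[2], dm[3], dm[4]))
  for (y in seq_len(dm[4])) {
    for (j in seq_len(dm[3])) {
      ku <- resample_to_k(svolume$frames[, , j, y], svolume$calibration)
      out[, , j, y] <- reconstruct_bscan(ku)
    }
  }
  proto <- svolume$protocol
  proto$n_depth <- nd
  new_oct_volume(out, proto, provenance = list(reconstructed = TRUE))
}

#' Log-scaled structural volume
#'
#' Amplitude decibels `20 log10(|c| + eps)` per voxel, averaged over the
#' repeats at each slow position (the standard display/segmentation image).
#' The `eps` guard keeps zero-amplitude voxels finite.
#'
#' @param volume an `oct_volume`.
#' @param eps additive guard before the logarithm.
#' @return a `structural_volume`: real array
#'   `[n_depth, n_alines, n_positions]` with a `display_range` attribute.
#' @export
to_log_structural <- function(volume, eps = 1e-12) {
  stopifnot(inherits(volume, "oct_volume"))
  dm <- dim(volume$frames)
  frames <- cpp_log_structural(volume$frames, dm, eps)
  sub <- frames[seq(1, length(frames), by = max(1L, length(frames) %/% 200000L))]
  structure(list(
    frames = frames,
    protocol = volume$protocol,
    display_range = as.numeric(quantile(sub, c(0.01, 0.99))),
    normalized = FALSE,
    norm_log = NULL
  ), class = "structural_volume")
}

#' @export
print.structural_volume <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<structural_volume> %d depth x %d alines x %d positions%s\n",
              d[1], d[2], d[3], if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Normalize per-frame reflectance to a common dynamic range
#'
#' Real acquisitions drift in overall signal strength between B-scans, which
#' would otherwise leak into the flow contrast. Each structural frame is
#' affinely remapped so its low/high percentiles land on a common reference
#' range (by default the across-volume median of the per-frame percentiles),
#' and the per-frame mapping is recorded in `norm_log`. Applying the
#' normalization twice is a no-op.
#'
#' @param svolume a `structural_volume`.
#' @param p_lo,p_hi percentiles anchoring the affine map.
#' @param ref_range optional length-2 reference range; defaults to the median
#'   of the per-frame `(p_lo, p_hi)` percentiles.
#' @return the normalized `structural_volume`.
#' @export
normalize_reflectance <- function(svolume, p_lo = 0.01, p_hi = 0.99,
                                  ref_range = NULL) {
  stopifnot(inherits(svolume, "structural_volume"))
  ny <- dim(svolume$frames)[3]
  qs <- t(vapply(seq_len(ny), function(y) {
    as.numeric(quantile(svolume$frames[, , y], c(p_lo, p_hi)))
  }, numeric(2)))
  ref_range <- ref_range %||% c(median(qs[, 1]), median(qs[, 2]))
  log_rows <- vector("list", ny)
  for (y in seq_len(ny)) {
    lo <- qs[y, 1]
    hi <- qs[y, 2]
    if (hi - lo < 1e-12) {
      warn(sprintf("frame %d is constant; left unchanged by normalization", y))
      scale <- 1
      offset <- 0
    } else {
      scale <- (ref_range[2] - ref_range[1]) / (hi - lo)
      offset <- ref_range[1] - lo * scale
      svolume$frames[, , y] <- svolume$frames[, , y] * scale + offset
    }
    log_rows[[y]] <- tibble(position = y, p_lo = lo, p_hi = hi,
                            scale = scale, offset = offset)
  }
  svolume$normalized <- TRUE
  svolume$norm_log <- dplyr::bind_rows(log_rows)
  svolume$display_range <- ref_range
  svolume
}

#' Structural image quality score
#'
#' Operationalizes "exclude poor-quality volumes" as an SNR score in dB: the
#' 99th-percentile signal below the top background rows minus the median of
#' the top `background_rows` depth rows (assumed tissue-free). Volumes scoring
#' below `min_snr_db` fail.
#'
#' @param svolume a `structural_volume` (un-normalized values are assumed).
#' @param min_snr_db pass/fail threshold in dB.
#' @param background_rows number of top depth rows treated as background.
#' @return a list with `pass` (logical) and `score_db`.
#' @export
assess_quality <- function(svolume, min_snr_db = 15, background_rows = 10) {
  stopifnot(inherits(svolume, "structural_volume"))
  nr <- dim(svolume$frames)[1]
  bg_rows <- seq_len(min(background_rows, nr))
  background <- median(svolume$frames[bg_rows, , ])
  tissue <- svolume$frames[-bg_rows, , , drop = FALSE]
  signal <- as.numeric(quantile(tissue, 0.99))
  score <- signal - background
  list(pass = score >= min_snr_db, score_db = score)
}
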