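# Spectral-fringe synthesis: the inverse of SD-OCT reconstruction, used to
# exercise k-space resampling and FFT reconstruction against known truth.

#' Spectrometer wavelength-to-wavenumber calibration
#'
#' Models a line-scan spectrometer sampled uniformly in wavelength, which is
#' the usual reason SD-OCT spectra are non-uniform in wavenumber `k = 2*pi /
#' lambda` and must be resampled before the FFT. With `bandwidth_nm = 0` the
#' calibration degenerates to a linear-in-k ramp (useful for identity tests).
#'
#' @param n_spectral number of spectrometer pixels.
#' @param center_wavelength_nm,bandwidth_nm spectral range sampled uniformly
#'   in wavelength.
#' @return an object of class `spectral_calibration`: a list with `wavenumber`
#'   (strictly monotone, length `n_spectral`) and the generating parameters.
#' @export
wavelength_calibration <- function(n_spectral,
                                   center_wavelength_nm = 850,
                                   bandwidth_nm = 240) {
  if (bandwidth_nm <= 0) {
    k <- seq(1, 2, length.out = n_spectral)
  } else {
    lambda <- seq(center_wavelength_nm - bandwidth_nm / 2,
                  center_wavelength_nm + bandwidth_nm / 2,
                  length.out = n_spectral)
    k <- 2 * pi / lambda  # decreasing in pixel
  }
  structure(list(wavenumber = k,
                 center_wavelength_nm = center_wavelength_nm,
                 bandwidth_nm = bandwidth_nm),
            class = "spectral_calibration")
}

#' Linear-in-wavenumber calibration
#'
#' @param n_spectral number of spectrometer pixels.
#' @return a `spectral_calibration` whose wavenumber axis is exactly uniform.
#' @export
linear_k_calibration <- function(n_spectral) {
  structure(list(wavenumber = seq(1, 2, length.out = n_spectral),
                 center_wavelength_nm = NA_real_, bandwidth_nm = 0),
            class = "spectral_calibration")
}

check_calibration <- function(calibration, n_spectral = NULL) {
  k <- calibration$wavenumber
  if (is.null(k) || anyNA(k)) {
    abort("calibration has missing wavenumbers", class = "octapipe_data_error")
  }
  dk <- diff(k)
  if (!(all(dk > 0) || all(dk < 0))) {
    abort("calibration must be strictly monotone in spectrometer pixel",
          class = "octapipe_data_error")
  }
  if (!is.null(n_spectral) && length(k) != n_spectral) {
    abort("calibration length does not match n_spectral",
          class = "octapipe_data_error")
  }
  invisible(k)
}

# Fringe basis: uniform-k sample index t(k) in [0, n_spectral - 1].
k_to_index <- function(k) {
  kr <- range(k)
  (k - kr[1]) / ((kr[2] - kr[1]) / (length(k) - 1))
}

#' Synthesize spectral interferograms from a complex OCT volume
#'
#' Inverse of the reconstruction chain: each A-line's depth profile `a_d`
#' (depth bins `d = 0 .. n_depth - 1`) becomes the real fringe
#' `S(p) = dc + sum_d 2 |a_d| cos(2 pi d t_p / n_spectral + phase_d)`, sampled
#' at the (generally non-uniform) wavenumbers of `calibration` via the
#' uniform-k fringe coordinate `t`. Resampling the result to uniform `k` and
#' applying [reconstruct_bscan()] recovers the original depth profile.
#'
#' @param volume an `oct_volume` with `n_depth <= n_spectral / 2`.
#' @param calibration a `spectral_calibration` of length
#'   `protocol$n_spectral`.
#' @param dc_level constant reference-arm offset added to every fringe.
#' @return a `spectral_volume`: real array
#'   `[n_spectral, n_alines, n_repeats, n_positions]` plus the calibration.
#' @export
synthesize_spectra <- function(volume, calibration = NULL, dc_level = 1) {
  stopifnot(inherits(volume, "oct_volume"))
  proto <- volume$protocol
  ns <- proto$n_spectral
  nd <- dim(volume$frames)[1]
  if (ns < 2 * nd) {
    abort("n_spectral must be at least twice n_depth", class = "octapipe_data_error")
  }
  calibration <- calibration %||% wavelength_calibration(ns)
  k <- check_calibration(calibration, ns)
  tp <- k_to_index(k)
  d <- 0:(nd - 1)
  basis <- exp(2i * pi * outer(tp, d) / ns)  # [ns, nd]
  dm <- dim(volume$frames)
  out <- array(0, dim = c(ns, dm[2], dm[3], dm[4]))
  for (y in seq_len(dm[4])) {
    for (j in seq_len(dm[3])) {
      a <- volume$frames[, , j, y]
      out[, , j, y] <- 2 * Re(basis %*% a) + dc_level
    }
  }
  structure(list(frames = out, calibration = calibration, protocol = proto),
            class = "spectral_volume")
}

#' @export
print.spectral_volume <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<spectral_volume> %d spectral px x %d alines x %d repeats x %d positions\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}
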