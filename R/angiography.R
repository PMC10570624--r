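# OCTA computation: complex-difference flow contrast from repeated B-scans.

#' Align the bulk phase of repeated complex frames
#'
#' Multiplies every frame after the first by a unit complex factor per A-line
#' — the phase of the inner product with the first frame's A-line — which
#' maximizes correlation with the reference and removes per-A-line bulk phase
#' jitter. Static scenes that differ only by a global or per-A-line phase
#' become identical, so their complex difference vanishes.
#'
#' @param frames complex array `[n_depth, n_alines, n_repeats]` at one slow
#'   position.
#' @return the phase-aligned frames (same shape).
#' @export
bulk_phase_align <- function(frames) {
  stopifnot(length(dim(frames)) == 3)
  nrep <- dim(frames)[3]
  if (nrep < 2) {
    abort("bulk_phase_align needs at least 2 repeated frames",
          class = "octapipe_data_error")
  }
  ref <- frames[, , 1]
  for (j in 2:nrep) {
    ip <- colSums(Conj(frames[, , j]) * ref)  # per A-line inner product
    phase <- ip / pmax(Mod(ip), .Machine$double.xmin)
    frames[, , j] <- sweep(frames[, , j], 2, phase, `*`)
  }
  frames
}

#' Complex-difference OCTA frame from repeated B-scans
#'
#' The flow contrast at one slow position is the voxelwise mean magnitude of
#' the complex difference between sequential repeats:
#' `mean_i |C_(i+1) - C_i|`, `i = 1 .. n_repeats - 1`. Static tissue with an
#' unchanged speckle pattern cancels exactly; decorrelated (flowing) voxels do
#' not.
#'
#' @param frames complex array `[n_depth, n_alines, n_repeats]` at one slow
#'   position.
#' @param phase_align apply [bulk_phase_align()] first (default `TRUE`).
#' @return a non-negative real matrix `[n_depth, n_alines]`.
#' @export
compute_octa <- function(frames, phase_align = TRUE) {
  stopifnot(length(dim(frames)) == 3)
  nrep <- dim(frames)[3]
  if (nrep < 2) {
    abort("OCTA needs at least 2 repeated frames per position",
          class = "octapipe_data_error")
  }
  if (phase_align) frames <- bulk_phase_align(frames)
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (i in seq_len(nrep - 1)) {
    acc <- acc + Mod(frames[, , i + 1] - frames[, , i])
  }
  acc / (nrep - 1)
}

#' Compute the OCTA volume from a repeated-frame complex volume
#'
#' Applies [compute_octa()] at every slow position, yielding one angiographic
#' B-scan per position.
#'
#' @param volume an `oct_volume`.
#' @param phase_align apply per-A-line bulk phase alignment before
#'   differencing.
#' @return an `octa_volume`: real array `[n_depth, n_alines, n_positions]`
#'   with `n_pairs_used = n_repeats - 1`.
#' @export
compute_octa_volume <- function(volume, phase_align = TRUE) {
  stopifnot(inherits(volume, "oct_volume"))
  dm <- dim(volume$frames)
  if (dm[3] < 2) {
    abort("OCTA needs at least 2 repeated frames per position",
          class = "octapipe_data_error")
  }
  out <- cpp_octa_volume(volume$frames, dm, phase_align)
  structure(list(frames = out, protocol = volume$protocol,
                 n_pairs_used = dm[3] - 1L, phase_aligned = phase_align),
            class = "octa_volume")
}

#' @export
print.octa_volume <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<octa_volume> %d depth x %d alines x %d positions; %d sequential pairs%s\n",
              d[1], d[2], d[3], x$n_pairs_used,
              if (isTRUE(x$phase_aligned)) ", phase-aligned" else ""))
  invisible(x)
}
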