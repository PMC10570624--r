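# Retinal layer segmentation: three reference surfaces found as minimum-cost
# depth paths over axial-gradient evidence, and plexus slab masks.
#
# Depth convention: all boundary maps are 0-based depth bins (bin d lives in
# array row d + 1), matching the phantom's ground-truth maps.

# Minimum-cost depth path across A-lines by dynamic programming (compiled).
# evidence: matrix [n_depth, n_alines], larger = better.
# Returns integer depth rows (1-based) of the path.
dp_surface_path <- function(evidence, smoothness = 0.5, max_jump = 3L) {
  cpp_dp_path(evidence, smoothness, as.integer(max_jump))
}

# Snap each column of a DP path to the local evidence maximum within a small
# window: the path provides robust tracking, the snap provides unbiased
# per-column localization on flat-peaked evidence.
snap_to_peak <- function(evidence, path, window = 2L) {
  nd <- nrow(evidence)
  vapply(seq_along(path), function(x) {
    lo <- max(1L, path[x] - window)
    hi <- min(nd, path[x] + window)
    lo + which.max(evidence[lo:hi, x]) - 1L
  }, integer(1))
}

# Parabolic sub-pixel refinement of a depth path on its evidence.
subpixel_refine <- function(evidence, path) {
  nd <- nrow(evidence)
  out <- as.numeric(path)
  for (x in seq_along(path)) {
    d <- path[x]
    if (d > 1 && d < nd) {
      y1 <- evidence[d - 1, x]
      y2 <- evidence[d, x]
      y3 <- evidence[d + 1, x]
      den <- y1 - 2 * y2 + y3
      if (is.finite(den) && abs(den) > 1e-12) {
        delta <- 0.5 * (y1 - y3) / den
        out[x] <- d + max(-0.5, min(0.5, delta))
      }
    }
  }
  out
}

#' Detect the three retinal reference surfaces
#'
#' Finds, per B-scan, the retinal surface (vitreous entry), the IPL/INL
#' junction and the RPE as minimum-cost depth paths over axial
#' intensity-gradient evidence: the surface and the RPE on the dark-to-bright
#' channel, the IPL/INL junction on the bright-to-dark channel. Paths are
#' regularized by a smoothness penalty on depth jumps between adjacent
#' A-lines; surfaces are found in order with the anatomical ordering
#' (surface < junction < RPE) enforced as a hard search constraint, refined to
#' sub-pixel by parabolic interpolation, and median-filtered across the
#' en-face plane.
#'
#' @param svolume a (preferably normalized) `structural_volume`.
#' @param smoothness penalty per pixel of depth jump between adjacent A-lines,
#'   in evidence (dB/px) units.
#' @param max_jump maximum depth jump between adjacent A-lines considered by
#'   the path search.
#' @param blur_sigma_z,blur_sigma_x axial and lateral Gaussian pre-smoothing
#'   (px) of each B-scan before the gradient; the lateral kernel is wider
#'   because boundaries vary slowly along the fast axis while static speckle
#'   does not.
#' @param blur_sigma_y Gaussian pre-smoothing across slow positions. Static
#'   speckle is independent between B-scans while the surfaces vary slowly,
#'   so averaging across neighbouring positions suppresses the main noise
#'   source of noiseless (speckle-limited) volumes.
#' @param min_retina_px minimum surface-to-RPE separation enforced when
#'   searching for the RPE.
#' @param junction_frac the IPL/INL junction is searched between
#'   `surface + min_inner_px` and `surface + junction_frac * (RPE - surface)`.
#' @param min_inner_px see `junction_frac`.
#' @param median_k kernel size of the final 2-D median filter on each map.
#' @return a `layer_boundaries` object: maps `superficial`, `ipl_inl`, `rpe`
#'   (`[n_positions, n_alines]`, 0-based depth bins, sub-pixel).
#' @export
detect_boundaries <- function(svolume, smoothness = 0.5, max_jump = 3L,
                              blur_sigma_z = 1.5, blur_sigma_x = 3,
                              blur_sigma_y = 2.5, min_retina_px = 30L,
                              junction_frac = 0.55, min_inner_px = 8L,
                              median_k = 5L) {
  stopifnot(inherits(svolume, "structural_volume"))
  dm <- dim(svolume$frames)
  nd <- dm[1]
  nx <- dm[2]
  ny <- dm[3]
  sup <- matrix(0, ny, nx)
  ipl <- matrix(0, ny, nx)
  rpe <- matrix(0, ny, nx)
  neg_inf <- -1e9
  vol <- svolume$frames
  if (blur_sigma_y > 0 && ny > 1) {
    dim(vol) <- c(nd * nx, ny)
    vol <- gaussian_blur_2d(vol, 0, blur_sigma_y)
    dim(vol) <- c(nd, nx, ny)
  }
  for (y in seq_len(ny)) {
    img <- gaussian_blur_2d(vol[, , y], blur_sigma_z, blur_sigma_x)
    grad <- img * 0
    grad[2:(nd - 1), ] <- (img[3:nd, ] - img[1:(nd - 2), ]) / 2
    if (max(grad) - min(grad) < 1e-6) {
      abort(sprintf("no gradient structure in B-scan %d; segmentation failed", y),
            class = "octapipe_segmentation_error")
    }
    # 1) retinal surface: strongest dark-to-bright transition
    p_sup <- snap_to_peak(grad, dp_surface_path(grad, smoothness, max_jump))
    # 2a) RPE body: the brightest band well below the surface
    ev <- img
    mask_rows <- outer(seq_len(nd), p_sup + min_retina_px, `<`)
    ev[mask_rows] <- neg_inf
    p_bright <- dp_surface_path(ev, smoothness, max_jump)
    # 2b) RPE surface: strongest dark-to-bright gradient just above the body
    ev <- grad
    bad <- outer(seq_len(nd), p_bright - 6L, `<`) |
      outer(seq_len(nd), p_bright + 2L, `>`)
    ev[bad | mask_rows] <- neg_inf
    p_rpe <- snap_to_peak(ev, dp_surface_path(ev, smoothness, max_jump))
    # 3) IPL/INL junction: bright-to-dark transition between them
    ev <- -grad
    lo <- p_sup + min_inner_px
    hi <- p_sup + junction_frac * (p_rpe - p_sup)
    bad <- outer(seq_len(nd), lo, `<`) | outer(seq_len(nd), hi, `>`)
    ev[bad] <- neg_inf
    p_ipl <- snap_to_peak(ev, dp_surface_path(ev, smoothness, max_jump))
    # sub-pixel refinement; +0.5 converts gradient-vertex position (centered
    # between the two voxels of the step) to the first row of the new layer,
    # -1 converts 1-based rows to 0-based depth bins
    sup[y, ] <- subpixel_refine(grad, p_sup) + 0.5 - 1
    rpe[y, ] <- subpixel_refine(grad, p_rpe) + 0.5 - 1
    ipl[y, ] <- subpixel_refine(-grad, p_ipl) + 0.5 - 1
  }
  sup <- median_filter_2d(sup, median_k)
  ipl <- median_filter_2d(ipl, median_k)
  rpe <- median_filter_2d(rpe, median_k)
  # hard ordering constraint
  ipl <- pmin(pmax(ipl, sup + 1), rpe - 1)
  new_layer_boundaries(sup, ipl, rpe, nd)
}

new_layer_boundaries <- function(superficial, ipl_inl, rpe, n_depth) {
  stopifnot(all(dim(superficial) == dim(ipl_inl)),
            all(dim(superficial) == dim(rpe)))
  if (any(superficial >= ipl_inl) || any(ipl_inl >= rpe)) {
    abort("layer boundaries violate superficial < ipl_inl < rpe",
          class = "octapipe_segmentation_error")
  }
  if (any(superficial < 0) || any(rpe >= n_depth)) {
    abort("layer boundaries outside the depth range",
          class = "octapipe_segmentation_error")
  }
  structure(list(superficial = superficial, ipl_inl = ipl_inl, rpe = rpe,
                 n_depth = as.integer(n_depth)),
            class = "layer_boundaries")
}

#' @export
print.layer_boundaries <- function(x, ...) {
  cat(sprintf("<layer_boundaries> %d x %d maps; mean depths: surface %.1f, IPL/INL %.1f, RPE %.1f (bins of %d)\n",
              nrow(x$superficial), ncol(x$superficial),
              mean(x$superficial), mean(x$ipl_inl), mean(x$rpe), x$n_depth))
  invisible(x)
}

#' Build a plexus slab mask from layer boundaries
#'
#' The superficial slab extends downward from the retinal surface:
#' `[surface, surface + widen_px)`. The deep slab is centered `shift_px` below
#' the IPL/INL junction (placing it on the OPL) and spans `widen_px` depth
#' bins symmetric about the center, resolved toward the shallow side when
#' `widen_px` is even. Slabs are clipped at the volume's depth limits; clipped
#' columns are recorded in the `clipped` attribute and reported.
#'
#' With `shift_px = "auto"` the deep-slab center is instead placed at the
#' depth (between junction and RPE) whose mean OCTA signal is maximal — an
#' extension for when the manual shift is unknown; `octa` must then be given.
#'
#' @param boundaries a `layer_boundaries`.
#' @param plexus `"superficial"` or `"deep"`.
#' @param widen_px slab thickness in depth bins; 10 to 20 recommended.
#' @param shift_px deep-slab center offset below the junction (ignored for the
#'   superficial slab), or `"auto"`.
#' @param octa an `octa_volume`, required for `shift_px = "auto"`.
#' @return a `plexus_mask`: logical array `[n_depth, n_alines, n_positions]`.
#' @export
make_plexus_mask <- function(boundaries, plexus = c("superficial", "deep"),
                             widen_px = 15L, shift_px = 12L, octa = NULL) {
  plexus <- match.arg(plexus)
  stopifnot(inherits(boundaries, "layer_boundaries"))
  widen_px <- as.integer(widen_px)
  if (widen_px < 1) abort("widen_px must be >= 1", class = "octapipe_config_error")
  if (widen_px < 10 || widen_px > 20) {
    warn(sprintf("widen_px = %d is outside the recommended 10..20 range", widen_px))
  }
  nd <- boundaries$n_depth
  ny <- nrow(boundaries$superficial)
  nx <- ncol(boundaries$superficial)
  if (identical(shift_px, "auto")) {
    if (plexus == "superficial") {
      shift_px <- 0L
    } else {
      if (is.null(octa)) {
        abort("shift_px = \"auto\" requires the octa volume", class = "octapipe_config_error")
      }
      shift_px <- auto_deep_shift(boundaries, octa)
    }
  }
  shift_px <- as.integer(shift_px)
  if (plexus == "superficial") {
    start <- round(boundaries$superficial)  # 0-based first bin
  } else {
    center <- round(boundaries$ipl_inl) + shift_px
    start <- center - widen_px %/% 2L
    if (all(start > boundaries$rpe)) {
      abort("deep slab lies entirely below the RPE; check shift_px",
            class = "octapipe_config_error")
    }
  }
  end <- start + widen_px - 1L
  start_c <- pmax(start, 0)
  end_c <- pmin(end, nd - 1L)
  clipped <- which(start_c != start | end_c != end, arr.ind = TRUE)
  if (nrow(clipped) > 0) {
    inform(sprintf("%d slab columns clipped at the depth limits", nrow(clipped)))
  }
  mask <- array(FALSE, dim = c(nd, nx, ny))
  drow <- seq_len(nd) - 1L  # 0-based bins
  for (y in seq_len(ny)) {
    lo <- matrix(start_c[y, ], nd, nx, byrow = TRUE)
    hi <- matrix(end_c[y, ], nd, nx, byrow = TRUE)
    mask[, , y] <- drow >= lo & drow <= hi
  }
  structure(list(mask = mask, plexus = plexus, widen_px = widen_px,
                 shift_px = if (plexus == "deep") shift_px else NA_integer_,
                 clipped = clipped),
            class = "plexus_mask")
}

# Extension: center the deep slab on the depth of maximal mean OCTA signal
# between the junction and the RPE (relative to the junction).
auto_deep_shift <- function(boundaries, octa) {
  stopifnot(inherits(octa, "octa_volume"))
  nd <- dim(octa$frames)[1]
  max_off <- max(1, floor(max(boundaries$rpe - boundaries$ipl_inl)))
  prof <- numeric(max_off)
  jr <- round(boundaries$ipl_inl)  # [ny, nx]
  for (off in seq_len(max_off)) {
    rows <- jr + off + 1L  # 1-based row at offset
    ok <- rows >= 1 & rows <= nd & (jr + off) < round(boundaries$rpe)
    if (!any(ok)) break
    idx <- which(ok, arr.ind = TRUE)  # (position, aline)
    prof[off] <- mean(octa$frames[cbind(rows[idx], idx[, 2], idx[, 1])])
  }
  which.max(prof)
}

#' @export
print.plexus_mask <- function(x, ...) {
  cat(sprintf("<plexus_mask> %s slab, widen %d px%s; %d clipped columns\n",
              x$plexus, x$widen_px,
              if (!is.na(x$shift_px)) sprintf(", shift %d px", x$shift_px) else "",
              nrow(x$clipped)))
  invisible(x)
}

#' Apply a plexus slab mask to an OCTA volume
#'
#' Voxelwise product: outside-mask voxels become exactly zero.
#'
#' @param octa an `octa_volume`.
#' @param mask a `plexus_mask` of matching shape.
#' @return the masked `octa_volume`.
#' @export
apply_mask <- function(octa, mask) {
  stopifnot(inherits(octa, "octa_volume"), inherits(mask, "plexus_mask"))
  if (!all(dim(octa$frames) == dim(mask$mask))) {
    abort("OCTA volume and mask shapes differ", class = "octapipe_data_error")
  }
  octa$frames <- octa$frames * mask$mask
  octa$plexus <- mask$plexus
  octa
}
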