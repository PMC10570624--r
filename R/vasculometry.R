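# Quantification of en-face angiograms: binarization, windowed vessel area
# density, and skeleton-based fragmentation metrics.

#' Binarize an en-face angiogram
#'
#' `"otsu"` applies a global Otsu threshold on a 256-bin histogram of the
#' map's range; `"fixed"` uses the supplied value. Foreground is
#' above-threshold. A constant map cannot be thresholded and returns
#' all-background with a warning.
#'
#' @param map an `enface_map` or numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param value threshold for `method = "fixed"`.
#' @return a `binary_vessel_map` (logical matrix) with `threshold_method` and
#'   `threshold_value` attributes.
#' @export
binarize <- function(map, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  m <- unclass(map)
  attributes(m) <- list(dim = dim(m))
  rng <- range(m)
  if (method == "otsu") {
    if (diff(rng) < 1e-12) {
      warn("constant map: Otsu threshold undefined, returning all background")
      thr <- rng[2]
      fg <- matrix(FALSE, nrow(m), ncol(m))
    } else {
      scaled <- (m - rng[1]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1), levels = 256)
      thr <- rng[1] + t01 * diff(rng)
      fg <- m > thr
    }
  } else {
    if (is.null(value)) abort("method = \"fixed\" needs a threshold value",
                              class = "octapipe_config_error")
    thr <- value
    fg <- m > thr
  }
  structure(fg, class = c("binary_vessel_map", "matrix", "array"),
            threshold_method = method, threshold_value = as.numeric(thr))
}

#' Windowed vessel area density
#'
#' Tiles the binary map with non-overlapping `window_px` x `window_px`
#' windows anchored at the top-left corner and reports, per window, the
#' white-pixel fraction. Partial windows at the right/bottom edges are
#' dropped (and counted in the `dropped_px` attribute), so the sum of
#' `density * window_px^2` over all windows equals the white-pixel count of
#' the tiled region exactly.
#'
#' @param binary a `binary_vessel_map` or logical matrix.
#' @param window_px window edge length in pixels.
#' @return a `density_map`: matrix `[floor(H / window), floor(W / window)]`
#'   of densities in `[0, 1]`.
#' @export
vessel_area_density <- function(binary, window_px = 20L) {
  window_px <- as.integer(window_px)
  if (window_px < 1) abort("window_px must be >= 1", class = "octapipe_config_error")
  m <- matrix(as.numeric(binary), nrow(binary), ncol(binary))
  if (window_px > nrow(m) || window_px > ncol(m)) {
    abort("window larger than the map", class = "octapipe_data_error")
  }
  nwr <- nrow(m) %/% window_px
  nwc <- ncol(m) %/% window_px
  sub <- m[seq_len(nwr * window_px), seq_len(nwc * window_px), drop = FALSE]
  # exact integer window sums via row-group then column-group aggregation
  rg <- rowsum(sub, rep(seq_len(nwr), each = window_px))
  cg <- t(rowsum(t(rg), rep(seq_len(nwc), each = window_px)))
  out <- cg / window_px^2
  dropped <- sum(m) - sum(sub)
  if (dropped > 0 || nwr * window_px < nrow(m) || nwc * window_px < ncol(m)) {
    inform(sprintf("partial edge windows dropped (%d rows, %d cols of pixels)",
                   nrow(m) - nwr * window_px, ncol(m) - nwc * window_px))
  }
  structure(unname(out), class = c("density_map", "matrix", "array"),
            window_px = window_px,
            dropped_px = c(rows = nrow(m) - nwr * window_px,
                           cols = ncol(m) - nwc * window_px))
}

# Zhang-Suen morphological thinning to a 1-px, 8-connected skeleton.
skeletonize <- function(binary) {
  img <- matrix(as.integer(binary), nrow(binary), ncol(binary))
  nr <- nrow(img)
  nc <- ncol(img)
  pad <- function(m) {
    out <- matrix(0L, nr + 2L, nc + 2L)
    out[2:(nr + 1L), 2:(nc + 1L)] <- m
    out
  }
  shift <- function(p, dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(img)
      # neighbours P2..P9 clockwise from north (row - 1)
      P2 <- shift(p, -1, 0); P3 <- shift(p, -1, 1); P4 <- shift(p, 0, 1)
      P5 <- shift(p, 1, 1);  P6 <- shift(p, 1, 0);  P7 <- shift(p, 1, -1)
      P8 <- shift(p, 0, -1); P9 <- shift(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      } else {
        cond <- P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      }
      del <- img == 1L & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        img[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}

# 8-connected clusters among a set of pixel coordinates (matrix [n, 2]).
cluster_pixels_8 <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- coords[, 1] * 1e6 + coords[, 2]
  idx_of <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx_of)
  for (i in seq_len(n)) {
    for (dr in -1:1) {
      for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nk <- as.character((coords[i, 1] + dr) * 1e6 + coords[i, 2] + dc)
        j <- idx_of[[nk]]
        if (!is.null(j)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Skeleton-based vessel metrics
#'
#' Thins the binary vessel map to a 1-px-wide 8-connected skeleton
#' (Zhang-Suen), then counts endpoints (skeleton pixels with exactly one
#' skeleton neighbour), branch points (pixels with three or more neighbours,
#' with 8-adjacent branch pixels merged into one junction), the total vessel
#' length as the number of skeleton pixels (optionally diagonal-weighted),
#' and the number of disconnected skeleton pieces. Per-area values divide by
#' the total map pixel count.
#'
#' @param binary a `binary_vessel_map` or logical matrix.
#' @param diagonal_weighted if `TRUE`, length counts `sqrt(2)` per diagonal
#'   skeleton step instead of 1 per pixel.
#' @return a one-row tibble: `n_endpoints`, `n_branches`, `n_pieces`,
#'   `total_length_px`, `endpoints_per_area`, `branches_per_area`,
#'   `map_area_px`.
#' @export
skeleton_metrics <- function(binary, diagonal_weighted = FALSE) {
  skel <- skeletonize(binary)
  area <- length(skel)
  if (!any(skel)) {
    return(tibble(n_endpoints = 0L, n_branches = 0L, n_pieces = 0L,
                  total_length_px = 0, endpoints_per_area = 0,
                  branches_per_area = 0, map_area_px = area))
  }
  nb <- neighbor_count_8(skel)
  endpoints <- skel & nb == 1L
  branch_pix <- which(skel & nb >= 3L, arr.ind = TRUE)
  n_branches <- if (nrow(branch_pix) == 0) 0L else {
    length(unique(cluster_pixels_8(branch_pix)))
  }
  skel_pix <- which(skel, arr.ind = TRUE)
  n_pieces <- length(unique(cluster_pixels_8(skel_pix)))
  if (diagonal_weighted) {
    # pixels + extra sqrt(2)-1 per diagonal-only link, counted once per pair
    total_len <- sum(skel)
    diag_links <- 0L
    for (d in list(c(-1, -1), c(-1, 1))) {
      a <- skel_pix
      b <- cbind(a[, 1] + d[1], a[, 2] + d[2])
      key <- function(m) m[, 1] * 1e6 + m[, 2]
      diag_links <- diag_links + sum(key(b) %in% key(skel_pix))
    }
    total_len <- total_len + (sqrt(2) - 1) * diag_links
  } else {
    total_len <- sum(skel)
  }
  tibble(
    n_endpoints = sum(endpoints),
    n_branches = as.integer(n_branches),
    n_pieces = as.integer(n_pieces),
    total_length_px = as.numeric(total_len),
    endpoints_per_area = sum(endpoints) / area,
    branches_per_area = n_branches / area,
    map_area_px = area
  )
}

#' Quantify an en-face angiogram
#'
#' One call for the four quantitative vessel parameters: binarizes the map,
#' computes the windowed vessel area density, and the skeleton metrics.
#'
#' @param map an `enface_map`.
#' @param window_px density window edge length.
#' @param threshold_method,threshold_value passed to [binarize()].
#' @return a one-row tibble: `density_mean`, `endpoints_per_area`,
#'   `branches_per_area`, `length_px`, plus raw counts, `n_pieces`,
#'   `n_windows` and the threshold used.
#' @export
quantify_enface <- function(map, window_px = 20L,
                            threshold_method = c("otsu", "fixed"),
                            threshold_value = NULL) {
  threshold_method <- match.arg(threshold_method)
  bin <- binarize(map, threshold_method, threshold_value)
  dens <- vessel_area_density(bin, window_px)
  sk <- skeleton_metrics(bin)
  tibble(
    density_mean = mean(dens),
    endpoints_per_area = sk$endpoints_per_area,
    branches_per_area = sk$branches_per_area,
    length_px = sk$total_length_px,
    n_endpoints = sk$n_endpoints,
    n_branches = sk$n_branches,
    n_pieces = sk$n_pieces,
    n_windows = length(dens),
    threshold_value = attr(bin, "threshold_value")
  )
}
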