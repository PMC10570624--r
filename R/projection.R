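# En-face projection of volumes to 2-D frontal-view maps.

#' Project a volume to an en-face map
#'
#' Collapses the depth axis per (position, A-line) column: `"mip"` takes the
#' column maximum (the standard angiographic projection), `"mean"` averages —
#' over in-mask voxels only when a `plexus_mask` is supplied, so empty columns
#' map to 0 rather than being diluted by out-of-slab zeros.
#'
#' @param volume an `octa_volume`, `structural_volume`, or a 3-D array
#'   `[n_depth, n_alines, n_positions]`.
#' @param method `"mip"` or `"mean"`.
#' @param mask optional `plexus_mask` restricting the `"mean"` projection.
#' @return an `enface_map`: matrix `[n_positions, n_alines]` with `source`
#'   and `method` attributes.
#' @export
enface_project <- function(volume, method = c("mip", "mean"), mask = NULL) {
  method <- match.arg(method)
  src <- "array"
  if (inherits(volume, "octa_volume")) {
    src <- paste0("octa", if (!is.null(volume$plexus)) paste0("-", volume$plexus) else "")
    arr <- volume$frames
  } else if (inherits(volume, "structural_volume")) {
    src <- "structural"
    arr <- volume$frames
  } else {
    arr <- volume
  }
  stopifnot(length(dim(arr)) == 3)
  if (length(arr) == 0) abort("empty volume", class = "octapipe_data_error")
  nd <- dim(arr)[1]
  nx <- dim(arr)[2]
  ny <- dim(arr)[3]
  if (method == "mip") {
    out <- cpp_enface_mip(arr, dim(arr))
  } else {
    out <- matrix(0, ny, nx)
    for (y in seq_len(ny)) {
      sl <- arr[, , y]
      if (!is.null(mask)) {
        m <- mask$mask[, , y]
        s <- colSums(sl * m)
        n <- colSums(m)
        out[y, ] <- ifelse(n > 0, s / pmax(n, 1), 0)
      } else {
        out[y, ] <- colMeans(sl)
      }
    }
  }
  structure(out, class = c("enface_map", "matrix", "array"),
            source = src, method = method)
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("<enface_map> %d positions x %d alines; source %s, method %s; range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "source"), attr(x, "method"),
              min(x), max(x)))
  invisible(x)
}
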