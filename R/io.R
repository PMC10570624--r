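# TIFF + JSON-sidecar storage. tiff stores [0, 1] floats, so every array is
# affinely encoded on write with the (lo, hi) range recorded in the sidecar;
# reading inverts the map exactly (up to float32).

format_version <- "1.0"

encode01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo < .Machine$double.eps) hi <- lo + 1
  list(data = (x - lo) / (hi - lo), lo = lo, hi = hi)
}

write_pages <- function(pages, path) {
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
}

#' Write / read a complex OCT volume as paired float TIFF stacks
#'
#' The real and imaginary parts go to `<basename>_real.tif` and
#' `<basename>_imag.tif` as multi-page 32-bit float stacks in position-major,
#' repeat-minor page order, with a JSON sidecar `<basename>.json` carrying the
#' scan protocol, the seed, the value ranges used for the `[0, 1]` float
#' encoding, and a format version.
#'
#' @param volume an `oct_volume`.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return (invisibly) the sidecar path.
#' @export
write_oct_volume <- function(volume, dir, basename = "oct") {
  stopifnot(inherits(volume, "oct_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- dim(volume$frames)
  pages_re <- list()
  pages_im <- list()
  re <- encode01(Re(volume$frames))
  im <- encode01(Im(volume$frames))
  i <- 0L
  for (y in seq_len(dm[4])) {
    for (j in seq_len(dm[3])) {
      i <- i + 1L
      pages_re[[i]] <- re$data[, , j, y]
      pages_im[[i]] <- im$data[, , j, y]
    }
  }
  write_pages(pages_re, file.path(dir, paste0(basename, "_real.tif")))
  write_pages(pages_im, file.path(dir, paste0(basename, "_imag.tif")))
  sidecar <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(
    format_version = format_version,
    kind = "oct_volume",
    protocol = unclass(volume$protocol),
    seed = volume$seed,
    dim = dm,
    page_order = "position-major, repeat-minor",
    range_real = c(re$lo, re$hi),
    range_imag = c(im$lo, im$hi)
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_oct_volume
#' @export
read_oct_volume <- function(dir, basename = "oct") {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(basename, ".json")),
                                 simplifyVector = TRUE)
  stopifnot(identical(sidecar$kind, "oct_volume"))
  dm <- as.integer(sidecar$dim)
  pr <- tiff::readTIFF(file.path(dir, paste0(basename, "_real.tif")), all = TRUE)
  pi_ <- tiff::readTIFF(file.path(dir, paste0(basename, "_imag.tif")), all = TRUE)
  dec <- function(pages, rng) {
    arr <- array(0, dim = dm)
    i <- 0L
    for (y in seq_len(dm[4])) {
      for (j in seq_len(dm[3])) {
        i <- i + 1L
        arr[, , j, y] <- pages[[i]] * (rng[2] - rng[1]) + rng[1]
      }
    }
    arr
  }
  frames <- complex(real = dec(pr, sidecar$range_real),
                    imaginary = dec(pi_, sidecar$range_imag))
  dim(frames) <- dm
  proto <- do.call(scan_protocol, sidecar$protocol[c(
    "n_alines_per_bscan", "n_positions", "n_repeats", "n_spectral", "n_depth",
    "pixel_size_xy_um", "pixel_size_z_um")])
  new_oct_volume(frames, proto, seed = sidecar$seed)
}

#' Write / read a real-valued image stack with sidecar
#'
#' Generic storage for OCTA volumes, structural volumes, en-face maps and
#' boundary maps: a multi-page 32-bit float TIFF plus a JSON sidecar with the
#' encoding range and a `kind` tag.
#'
#' @param arr a numeric matrix or 3-D array (last dimension = pages).
#' @param path output TIFF path (`.json` sidecar written next to it).
#' @param kind free-form content tag stored in the sidecar.
#' @param meta optional named list merged into the sidecar.
#' @return (invisibly) the sidecar path.
#' @export
write_float_stack <- function(arr, path, kind = "stack", meta = list()) {
  enc <- encode01(arr)
  pages <- if (length(dim(arr)) == 3) {
    lapply(seq_len(dim(arr)[3]), function(i) enc$data[, , i])
  } else {
    list(enc$data)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write_pages(pages, path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(c(list(
    format_version = format_version, kind = kind,
    dim = dim(arr), range = c(enc$lo, enc$hi)
  ), meta), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_float_stack
#' @export
read_float_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                                 simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  dm <- as.integer(sidecar$dim)
  arr <- array(0, dim = dm)
  if (length(dm) == 3) {
    for (i in seq_len(dm[3])) arr[, , i] <- pages[[i]]
  } else {
    arr[, ] <- pages[[1]]
  }
  rng <- sidecar$range
  out <- arr * (rng[2] - rng[1]) + rng[1]
  attr(out, "kind") <- sidecar$kind
  out
}

#' Export an en-face or density map as an 8-bit pseudo-colour PNG
#'
#' For figures only: values are windowed at the given percentiles and mapped
#' either to grayscale or to a blue-to-red ramp (the usual display for vessel
#' density maps).
#'
#' @param map numeric matrix.
#' @param path output PNG path.
#' @param palette `"gray"` or `"blue-red"`.
#' @param percentiles display window.
#' @return (invisibly) `path`.
#' @export
export_map_png <- function(map, path, palette = c("gray", "blue-red"),
                           percentiles = c(0.01, 0.99)) {
  palette <- match.arg(palette)
  q <- quantile(map, percentiles)
  if (q[2] - q[1] < .Machine$double.eps) q[2] <- q[1] + 1
  z <- pmin(pmax((map - q[1]) / (q[2] - q[1]), 0), 1)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (palette == "gray") {
    png::writePNG(z, path)
  } else {
    ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))(as.vector(z)) / 255
    img <- array(ramp, dim = c(dim(z), 3))
    png::writePNG(img, path)
  }
  invisible(path)
}
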