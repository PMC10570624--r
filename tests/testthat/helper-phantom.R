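# Shared fixtures: small protocols and phantoms that keep the suite fast, and
# independent brute-force oracles used to check the implementation.

tiny_protocol <- function(nx = 48, ny = 32, nrep = 5, ns = 384, nd = 192,
                          z_um = 2) {
  scan_protocol(n_alines_per_bscan = nx, n_positions = ny, n_repeats = nrep,
                n_spectral = ns, n_depth = nd, pixel_size_z_um = z_um)
}

tiny_phantom_spec <- function(seed = 1, noise_floor = 0.02, ...) {
  phantom_spec(tiny_protocol(), noise_floor = noise_floor, seed = seed, ...)
}

# Independent direct DFT (no stats::fft): X[f] = sum_p x[p] exp(-2i pi p f / n)
direct_dft <- function(x) {
  n <- length(x)
  p <- 0:(n - 1)
  vapply(p, function(f) sum(x * exp(-2i * pi * p * f / n)), complex(1))
}

# Brute-force per-window density (independent double loop).
brute_density <- function(mask, w) {
  nwr <- nrow(mask) %/% w
  nwc <- ncol(mask) %/% w
  out <- matrix(0, nwr, nwc)
  for (i in seq_len(nwr)) {
    for (j in seq_len(nwc)) {
      s <- 0L
      for (r in ((i - 1) * w + 1):(i * w)) {
        for (cc in ((j - 1) * w + 1):(j * w)) s <- s + mask[r, cc]
      }
      out[i, j] <- s / w^2
    }
  }
  out
}

# Brute-force neighbour count of TRUE cells around (r, c).
brute_neighbors <- function(m, r, cc) {
  n <- 0L
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr
      c2 <- cc + dc
      if (rr >= 1 && rr <= nrow(m) && c2 >= 1 && c2 <= ncol(m) && m[rr, c2]) {
        n <- n + 1L
      }
    }
  }
  n
}

# Endpoint / branch-pixel counts on a skeleton by brute-force neighbour loops.
brute_skeleton_counts <- function(skel) {
  ep <- 0L
  bp <- list()
  for (r in seq_len(nrow(skel))) {
    for (cc in seq_len(ncol(skel))) {
      if (!skel[r, cc]) next
      nb <- brute_neighbors(skel, r, cc)
      if (nb == 1) ep <- ep + 1L
      if (nb >= 3) bp[[length(bp) + 1L]] <- c(r, cc)
    }
  }
  list(endpoints = ep, branch_pixels = if (length(bp)) do.call(rbind, bp) else
    matrix(0L, 0, 2))
}

# FWHM (in bins) of the magnitude peak of a spectrum's FFT.
peak_fwhm <- function(mag) {
  pk <- which.max(mag)
  half <- mag[pk] / 2
  lo <- pk
  while (lo > 1 && mag[lo] > half) lo <- lo - 1
  hi <- pk
  while (hi < length(mag) && mag[hi] > half) hi <- hi + 1
  hi - lo
}

# Long time-course tibble from a units x timepoints matrix.
tbl_from_wide <- function(Y, weeks = seq_len(ncol(Y))) {
  tibble::tibble(
    subject = rep(seq_len(nrow(Y)), times = ncol(Y)),
    eye = 1L,
    timepoint_weeks = rep(weeks, each = nrow(Y)),
    plexus = "deep",
    metric = "m",
    value = as.vector(Y)
  )
}
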