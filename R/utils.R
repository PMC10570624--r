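# Internal helpers shared across modules: seeded RNG scoping, child-seed
# derivation, small image utilities.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Streams of randomness for different (subject, eye, timepoint) combinations
#' are decoupled by hashing the master seed together with small integer tags
#' through a multiplicative congruential mix modulo the Mersenne prime
#' 2^31 - 1. Identical inputs always give the identical child seed, and any
#' single stream can be regenerated without replaying the others.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer tags (e.g. subject, eye, timepoint
#'   indices), combined in order.
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' child_seed(42, 1, 2, 3)
child_seed <- function(master, ...) {
  m <- 2147483647
  h <- (abs(as.numeric(master)) %% m)
  for (tag in c(...)) {
    h <- (h * 48271 + abs(as.numeric(tag)) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# 2-D median filter with odd square kernel; edges handled by replication.
median_filter_2d <- function(mat, k = 5) {
  stopifnot(k %% 2 == 1)
  if (k == 1) return(mat)
  cpp_median_filter(mat, as.integer(k))
}

# Separable Gaussian blur of a matrix, replicated edges; independent axial
# (row) and lateral (column) sigmas.
gaussian_blur_2d <- function(mat, sigma_row, sigma_col = sigma_row) {
  cpp_gaussian_blur(mat, sigma_row, sigma_col)
}

# Count of 8-neighbours that are TRUE, for a logical matrix.
neighbor_count_8 <- function(mat) {
  m <- matrix(0L, nrow(mat) + 2L, ncol(mat) + 2L)
  m[2:(nrow(mat) + 1L), 2:(ncol(mat) + 1L)] <- as.integer(mat)
  nr <- nrow(mat)
  nc <- ncol(mat)
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      acc <- acc + m[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
  }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
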