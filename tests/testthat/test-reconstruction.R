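test_that("reconstruct_bscan recovers integer-frequency fringes exactly", {
  ns <- 256
  p <- 0:(ns - 1)
  for (f in c(3, 40, 100)) {
    fr <- matrix(cos(2 * pi * f * p / ns), ncol = 1)
    bs <- reconstruct_bscan(fr)
    expect_equal(which.max(abs(bs[, 1])), f + 1)
    expect_equal(abs(bs[f + 1, 1]), 0.5, tolerance = 1e-10)
  }
  # constant spectrum -> all-zero A-line after DC removal
  bs0 <- reconstruct_bscan(matrix(7, ns, 1))
  expect_equal(max(abs(bs0)), 0, tolerance = 1e-12)
})

test_that("two-fringe reconstruction matches an independent direct DFT", {
  ns <- 128
  p <- 0:(ns - 1)
  x <- 2 * 0.8 * cos(2 * pi * 11 * p / ns + 0.3) +
    2 * 0.4 * cos(2 * pi * 37 * p / ns - 1.1)
  bs <- reconstruct_bscan(matrix(x, ncol = 1))[, 1]
  ref <- direct_dft(x - mean(x))[1:(ns / 2)] / ns
  expect_equal(max(abs(bs - ref)), 0, tolerance = 1e-6)
  pks <- sort(order(abs(bs), decreasing = TRUE)[1:2])
  expect_equal(pks, c(12, 38))
})

test_that("reconstruction is linear in the input frame", {
  ns <- 128
  fr <- matrix(rnorm(ns * 4), ns, 4)
  expect_equal(reconstruct_bscan(3.5 * fr), 3.5 * reconstruct_bscan(fr))
})

test_that("resampling an already linear-in-k frame is the identity", {
  ns <- 256
  cal <- linear_k_calibration(ns)
  fr <- matrix(rnorm(ns * 3), ns, 3)
  out <- resample_to_k(fr, cal)
  expect_equal(out, fr, tolerance = 1e-9)
})

test_that("resampling rejects degenerate calibrations and NaN frames", {
  ns <- 64
  cal <- linear_k_calibration(ns)
  cal$wavenumber[10] <- cal$wavenumber[9]  # repeated value
  expect_error(resample_to_k(matrix(0, ns, 1), cal),
               class = "octapipe_data_error")
  fr <- matrix(0, ns, 1)
  fr[5] <- NaN
  expect_error(resample_to_k(fr, linear_k_calibration(ns)),
               class = "octapipe_data_error")
})

test_that("k-resampling sharpens a chirped single-reflector fringe", {
  ns <- 1024
  cal <- wavelength_calibration(ns, 850, 240)
  tp <- octapipe:::k_to_index(cal$wavenumber)
  d <- 90
  fringe <- matrix(2 * cos(2 * pi * d * tp / ns), ncol = 1)
  mag_before <- abs(reconstruct_bscan(fringe)[, 1])
  mag_after <- abs(reconstruct_bscan(resample_to_k(fringe, cal))[, 1])
  expect_lt(peak_fwhm(mag_after), peak_fwhm(mag_before))
  expect_equal(which.max(mag_after), d + 1)
})

test_that("spectral synthesis round trip recovers reflector depths and magnitudes", {
  p <- scan_protocol(n_alines_per_bscan = 3, n_positions = 1, n_repeats = 1,
                     n_spectral = 2048, n_depth = 1024)
  a <- array(0 + 0i, dim = c(1024, 3, 1, 1))
  depths <- c(45, 120, 200)   # realistic retinal depth bins
  mags <- c(0.8, 0.5, 0.3)
  for (i in 1:3) a[depths[i] + 1, i, 1, 1] <- mags[i] * exp(1i * i)
  vol <- octapipe:::new_oct_volume(a, p)
  sp <- synthesize_spectra(vol, wavelength_calibration(2048, 850, 240))
  rec <- reconstruct_volume(sp)
  for (i in 1:3) {
    col <- abs(rec$frames[, i, 1, 1])
    expect_equal(which.max(col), depths[i] + 1)
    expect_equal(max(col), mags[i], tolerance = 0.01)
  }
})

test_that("zero volumes synthesize to constant (DC-only) spectra", {
  p <- scan_protocol(n_alines_per_bscan = 2, n_positions = 1, n_repeats = 1,
                     n_spectral = 128, n_depth = 64)
  vol <- octapipe:::new_oct_volume(array(0 + 0i, dim = c(64, 2, 1, 1)), p)
  sp <- synthesize_spectra(vol, dc_level = 3)
  expect_equal(max(sp$frames), 3)
  expect_equal(min(sp$frames), 3)
})

test_that("log-structural conversion applies 20 log10 with a finite guard", {
  p <- scan_protocol(n_alines_per_bscan = 2, n_positions = 1, n_repeats = 1,
                     n_spectral = 8, n_depth = 4)
  a <- array(complex(real = c(1, 10, 0, 1e-3), imaginary = 0), dim = c(4, 2, 1, 1))
  a[, 2, , ] <- a[, 1, , ]
  sv <- to_log_structural(octapipe:::new_oct_volume(a, p))
  expect_equal(sv$frames[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(sv$frames[2, 1, 1], 20, tolerance = 1e-9)
  expect_true(is.finite(sv$frames[3, 1, 1]))  # |c| = 0 stays finite
})

test_that("reflectance normalization aligns gain-shifted frames and is idempotent", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 12))
  sv <- to_log_structural(ph$volume)
  # frame 2 = frame 1 with a global amplitude gain x3 (+9.54 dB)
  sv$frames[, , 2] <- sv$frames[, , 1] + 20 * log10(3)
  out <- normalize_reflectance(sv)
  q1 <- quantile(out$frames[, , 1], c(0.01, 0.99))
  q2 <- quantile(out$frames[, , 2], c(0.01, 0.99))
  expect_equal(as.numeric(q1), as.numeric(q2), tolerance = 1e-6)
  # idempotent
  out2 <- normalize_reflectance(out)
  expect_equal(out2$frames, out$frames, tolerance = 1e-9)
})

test_that("constant frames pass through normalization with a warning", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 13))
  sv <- to_log_structural(ph$volume)
  sv$frames[, , 3] <- -40
  expect_warning(out <- normalize_reflectance(sv), "constant")
  expect_equal(out$frames[, , 3], sv$frames[, , 3])
})

test_that("quality score separates noise-only from structured volumes", {
  proto <- tiny_protocol()
  stack0 <- default_layer_stack()
  stack0$reflectivity <- rep(0, nrow(stack0))
  noise_spec <- phantom_spec(proto, layer_stack = stack0,
                             blood_reflectivity = 0, choroid_reflectivity = 0,
                             noise_floor = 0.05, seed = 14)
  sv_noise <- to_log_structural(generate_phantom(noise_spec)$volume)
  expect_false(assess_quality(sv_noise)$pass)

  good <- generate_phantom(tiny_phantom_spec(seed = 15))
  sv_good <- to_log_structural(good$volume)
  expect_true(assess_quality(sv_good)$pass)
  # -Inf threshold always passes
  expect_true(assess_quality(sv_noise, min_snr_db = -Inf)$pass)
})
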