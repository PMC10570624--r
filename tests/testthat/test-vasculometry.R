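test_that("binarization separates clean two-level maps and flags constants", {
  m <- matrix(0.1, 20, 20)
  m[5:10, 5:15] <- 0.9
  b <- binarize(m, "otsu")
  expect_identical(unclass(b), m > 0.5, ignore_attr = TRUE)
  b2 <- binarize(m, "fixed", value = 0.5)
  expect_identical(unclass(b2), m > 0.5, ignore_attr = TRUE)
  expect_warning(bc <- binarize(matrix(0.3, 5, 5), "otsu"), "constant")
  expect_false(any(bc))
})

test_that("binarized phantom en-face maps recover the true vessel area fraction", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 51))
  oc <- compute_octa_volume(ph$volume)
  sv <- normalize_reflectance(to_log_structural(ph$volume))
  bnd <- detect_boundaries(sv)
  mask <- make_plexus_mask(bnd, "deep", widen_px = 15,
                           shift_px = geometry_deep_shift(default_layer_stack(), 2))
  bin <- binarize(enface_project(apply_mask(oc, mask), "mip"), "otsu")
  expect_lt(abs(mean(bin) - mean(ph$truth$plexus_masks$deep)), 0.02)
})

test_that("density maps equal brute-force window counts exactly", {
  expect_equal(
    unclass(vessel_area_density(matrix(TRUE, 20, 20), 20))[1, 1], 1
  )
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE  # 100 of 400
  expect_equal(as.numeric(vessel_area_density(m, 20)), 0.25)
  set.seed(99)
  for (i in 1:50) {
    mm <- matrix(runif(100 * 100) < runif(1, 0.1, 0.6), 100, 100)
    d <- vessel_area_density(mm, 20)
    expect_identical(unclass(d), brute_density(mm, 20), ignore_attr = TRUE)
  }
})

test_that("density conservation: window sums equal white counts exactly", {
  set.seed(7)
  mm <- matrix(runif(97 * 103) < 0.3, 97, 103)  # forces dropped edges
  expect_message(d <- vessel_area_density(mm, 20), "dropped")
  tiled <- mm[1:80, 1:100]
  expect_identical(sum(d * 400), as.numeric(sum(tiled)))
  expect_error(vessel_area_density(matrix(TRUE, 10, 10), 20),
               class = "octapipe_data_error")
})

test_that("skeleton metrics are zero on empty maps", {
  sk <- skeleton_metrics(matrix(FALSE, 30, 30))
  expect_equal(sk$n_endpoints, 0L)
  expect_equal(sk$n_branches, 0L)
  expect_equal(sk$total_length_px, 0)
})

test_that("a thick straight line thins to its midline with two endpoints", {
  m <- matrix(FALSE, 40, 60)
  m[20:22, 11:40] <- TRUE  # 3 px thick, 30 px long
  sk <- skeleton_metrics(m)
  expect_equal(sk$n_endpoints, 2L)
  expect_equal(sk$n_branches, 0L)
  expect_equal(sk$n_pieces, 1L)
  expect_lte(abs(sk$total_length_px - 30), 3)  # Zhang-Suen end erosion
  # an already 1-px line is preserved exactly
  m1 <- matrix(FALSE, 10, 50)
  m1[5, 11:40] <- TRUE
  sk1 <- skeleton_metrics(m1)
  expect_equal(sk1$total_length_px, 30)
  expect_equal(sk1$n_endpoints, 2L)
  # cross-check against the brute-force neighbour-count oracle
  skel <- octapipe:::skeletonize(m)
  oracle <- brute_skeleton_counts(skel)
  expect_equal(sk$n_endpoints, oracle$endpoints)
})

test_that("a Y-shaped figure has three endpoints and one junction cluster", {
  m <- matrix(FALSE, 60, 60)
  # three 20-px arms from (30, 30)
  for (t in 0:20) {
    m[30, 30 + t] <- TRUE                      # east arm
    m[30 - t, 30 - round(t * 0.6)] <- TRUE     # north-west arm
    m[30 + t, 30 - round(t * 0.6)] <- TRUE     # south-west arm
  }
  sk <- skeleton_metrics(m)
  expect_equal(sk$n_endpoints, 3L)
  expect_equal(sk$n_branches, 1L)
  skel <- octapipe:::skeletonize(m)
  oracle <- brute_skeleton_counts(skel)
  expect_equal(sk$n_endpoints, oracle$endpoints)
  expect_gte(nrow(oracle$branch_pixels), 1)
})

test_that("cutting a skeleton line into pieces increases endpoints", {
  m <- matrix(FALSE, 20, 80)
  m[10, 6:75] <- TRUE
  base <- skeleton_metrics(m)
  for (k in c(1, 2, 3)) {
    cut <- m
    for (j in seq_len(k)) cut[10, 6 + j * 15] <- FALSE
    sk <- skeleton_metrics(cut)
    expect_equal(sk$n_endpoints, base$n_endpoints + 2L * k)
    expect_equal(sk$n_pieces, base$n_pieces + k)
  }
})

test_that("per-area metrics are stable under 2x2 tiling of the same pattern", {
  set.seed(11)
  ph <- generate_phantom(tiny_phantom_spec(seed = 52))
  truth <- ph$truth$plexus_masks$deep
  m1 <- skeleton_metrics(truth)
  big <- rbind(cbind(truth, truth), cbind(truth, truth))
  m4 <- skeleton_metrics(big)
  expect_lt(abs(m4$endpoints_per_area - m1$endpoints_per_area) /
              max(m1$endpoints_per_area, 1e-9), 0.35)
  expect_lt(abs(m4$total_length_px - 4 * m1$total_length_px) /
              m1$total_length_px / 4, 0.05)
})

test_that("quantify_enface bundles density and skeleton metrics", {
  m <- matrix(0, 40, 40)
  m[19:21, 6:35] <- 1
  q <- quantify_enface(m, window_px = 20, threshold_method = "fixed",
                       threshold_value = 0.5)
  expect_equal(q$n_endpoints, 2L)
  expect_equal(q$n_windows, 4L)
  expect_equal(q$density_mean, sum(m > 0.5) / 1600)
})
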