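test_that("scan protocol encodes the acquisition arithmetic", {
  p <- scan_protocol()
  expect_equal(p$n_alines_per_bscan, 500L)
  expect_equal(p$n_repeats, 5L)
  expect_equal(p$n_spectral, 2048L)
  expect_equal(n_frames(p), 2000L)
  expect_equal(n_octa_bscans(p), 400L)
  expect_error(scan_protocol(n_repeats = 0), class = "octapipe_config_error")
})

test_that("phantom generation is deterministic and shape-correct", {
  spec <- tiny_phantom_spec(seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$frames, b$volume$frames)
  expect_identical(a$truth$density, b$truth$density)
  expect_equal(dim(a$volume$frames), c(192, 48, 5, 32))
  # different seed changes the realization
  c2 <- generate_phantom(tiny_phantom_spec(seed = 6))
  expect_false(identical(a$volume$frames, c2$volume$frames))
})

test_that("static noiseless phantom has bit-identical repeats", {
  spec <- tiny_phantom_spec(
    seed = 2, noise_floor = 0,
    flow_decorrelation = c(superficial = 0, intermediate = 0, deep = 0)
  )
  ph <- generate_phantom(spec)
  for (j in 2:dim(ph$volume$frames)[3]) {
    expect_identical(ph$volume$frames[, , j, ], ph$volume$frames[, , 1, ])
  }
})

test_that("decorrelated lumens differ between repeats much more than tissue", {
  spec <- tiny_phantom_spec(seed = 3, noise_floor = 0)
  ph <- generate_phantom(spec)
  d <- abs(ph$volume$frames[, , 2, ] - ph$volume$frames[, , 1, ])
  lum <- unlist(ph$truth$lumen_voxels)
  expect_gt(mean(d[lum]), 5 * max(mean(d[-lum]), 1e-12))
})

test_that("phasor speckle model behaves like the gaussian limit", {
  spec <- tiny_phantom_spec(seed = 4, noise_floor = 0,
                            speckle_model = "phasor")
  ph <- generate_phantom(spec)
  d <- abs(ph$volume$frames[, , 2, ] - ph$volume$frames[, , 1, ])
  lum <- unlist(ph$truth$lumen_voxels)
  expect_gt(mean(d[lum]), 5 * max(mean(d[-lum]), 1e-12))
  # mean speckle intensity in the lumen matches the blood reflectivity
  expect_equal(mean(abs(ph$volume$frames[, , 1, ])[lum]^2),
               0.35, tolerance = 0.05)
})

test_that("ground-truth density maps equal brute-force recounts exactly", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 7))
  for (nm in names(ph$truth$plexus_masks)) {
    expect_identical(ph$truth$density[[nm]],
                     brute_density(ph$truth$plexus_masks[[nm]], 20L))
  }
})

test_that("ground-truth boundary maps are strictly ordered in depth", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 8))
  b <- ph$truth$boundaries
  expect_true(all(b$superficial < b$ipl_inl))
  expect_true(all(b$ipl_inl < b$rpe))
  expect_true(all(b$superficial >= 0))
  expect_true(all(b$rpe < tiny_protocol()$n_depth))
})

test_that("vessel trees referencing unknown layers are rejected", {
  proto <- tiny_protocol()
  trees <- default_vessel_trees(proto, seed = 1)
  trees$deep$plexus_depth_layer <- "NOSUCH"
  expect_error(phantom_spec(proto, vessel_trees = trees),
               class = "octapipe_config_error")
})

test_that("degeneration schedule validates monotonicity and clamps", {
  expect_error(
    degeneration_schedule(1:3, c(1, 0.5, 0.8), c(0, 0, 0), c(0, 0, 0)),
    class = "octapipe_config_error"
  )
  expect_error(
    degeneration_schedule(1:3, c(1, 1, 1), c(0.5, 0.2, 0.6), c(0, 0, 0)),
    class = "octapipe_config_error"
  )
  expect_warning(
    degeneration_schedule(1:2, c(1, 1), c(0, 1.2), c(0, 0)),
    "clamped"
  )
})

test_that("zero degeneration is the identity on the vessel trees", {
  spec <- tiny_phantom_spec(seed = 9)
  sch <- degeneration_schedule(1:2, c(1, 1), c(0, 0), c(0, 0))
  out <- apply_degeneration(spec, sch, 1, seed = 99)
  expect_identical(out$vessel_trees, spec$vessel_trees)
  expect_identical(out$layer_stack, spec$layer_stack)
})

test_that("full pruning empties the deep tree and its density truth", {
  spec <- tiny_phantom_spec(seed = 10)
  sch <- degeneration_schedule(1:2, c(1, 1), c(0, 1), c(0, 0))
  out <- apply_degeneration(spec, sch, 2, seed = 99)
  expect_length(out$vessel_trees$deep$segments, 0)
  ph <- generate_phantom(out)
  expect_true(all(ph$truth$density$deep == 0))
  # superficial tree untouched
  expect_identical(out$vessel_trees$superficial, spec$vessel_trees$superficial)
})

test_that("higher break rates produce more endpoints (Monte-Carlo over trees)", {
  sch <- degeneration_schedule(1:2, c(1, 1), c(0, 0), c(1, 4))
  n_ep <- matrix(0, 200, 2)
  for (i in 1:200) {
    spec <- phantom_spec(tiny_protocol(nx = 40, ny = 40), seed = i)
    for (t in 1:2) {
      out <- apply_degeneration(spec, sch, t, seed = i)
      st <- octapipe:::tree_skeleton_truth(out$vessel_trees$deep)
      n_ep[i, t] <- st$n_endpoints
    }
  }
  expect_gt(mean(n_ep[, 2]), mean(n_ep[, 1]))
})

test_that("ground-truth deep density is non-increasing along the schedule", {
  sch <- default_degeneration_schedule()
  for (seed in c(21, 22, 23)) {
    spec <- phantom_spec(tiny_protocol(nx = 40, ny = 40), seed = seed)
    dens <- vapply(seq_along(sch$timepoint_weeks), function(t) {
      out <- apply_degeneration(spec, sch, t, seed = seed)
      ras <- octapipe:::rasterize_tree(out$vessel_trees$deep, 40, 40)
      mean(ras$mask)
    }, numeric(1))
    expect_true(all(diff(dens) <= 1e-12))
  }
})
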