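flat_boundaries <- function(ny = 8, nx = 10, sup = 50, ipl = 80, rpe = 120,
                            nd = 160) {
  octapipe:::new_layer_boundaries(
    matrix(sup, ny, nx), matrix(ipl, ny, nx), matrix(rpe, ny, nx), nd
  )
}

empty_vessel_trees <- function() {
  mk <- function(layer) {
    structure(list(segments = list(), plexus_depth_layer = layer),
              class = "vessel_tree")
  }
  list(superficial = mk("GCL"), intermediate = mk("IPL"), deep = mk("OPL"))
}

test_that("flat boundaries at known depths are recovered to sub-pixel accuracy", {
  # the vitreous/GCL edge is recovered within 1 px everywhere; the weaker
  # interior edges are speckle-limited to ~1 px at a handful of columns
  ph <- generate_phantom(tiny_phantom_spec(seed = 30, noise_floor = 0,
                                           topography_amplitude_px = 0,
                                           vessel_trees = empty_vessel_trees()))
  sv <- normalize_reflectance(to_log_structural(ph$volume))
  bnd <- detect_boundaries(sv)
  tr <- ph$truth$boundaries
  expect_lt(max(abs(bnd$superficial - tr$superficial)), 1)
  for (nm in c("ipl_inl", "rpe")) {
    e <- abs(bnd[[nm]] - tr[[nm]])
    expect_lt(sqrt(mean(e^2)), 0.5)
    expect_lte(as.numeric(quantile(e, 0.99)), 1)
    expect_lt(max(e), 2)
  }
})

test_that("a 30 px tilted surface ramp is recovered within 2 px", {
  proto <- tiny_protocol(nx = 64, ny = 24)
  spec <- phantom_spec(proto, topography_amplitude_px = 0, noise_floor = 0,
                       seed = 31, vessel_trees = empty_vessel_trees())
  ramp <- matrix(rep(seq(0, 30, length.out = 64), each = 24), 24, 64)
  spec$topography <- ramp
  ph <- generate_phantom(spec)
  sv <- normalize_reflectance(to_log_structural(ph$volume))
  bnd <- detect_boundaries(sv)
  tr <- ph$truth$boundaries
  expect_lt(max(abs(bnd$superficial - tr$superficial)), 2)
  expect_lt(max(abs(bnd$rpe - tr$rpe)), 2)
  e <- abs(bnd$ipl_inl - tr$ipl_inl)
  expect_lte(as.numeric(quantile(e, 0.99)), 2)  # speckle-limited corners
  expect_lt(max(e), 3)
})

test_that("segmentation rejects volumes without gradient structure", {
  proto <- tiny_protocol(nx = 16, ny = 4)
  sv <- structure(list(frames = array(3, dim = c(192, 16, 4)),
                       protocol = proto, display_range = c(0, 1),
                       normalized = TRUE, norm_log = NULL),
                  class = "structural_volume")
  expect_error(detect_boundaries(sv), class = "octapipe_segmentation_error")
})

test_that("boundary ordering is a hard invariant of the container", {
  expect_error(
    octapipe:::new_layer_boundaries(matrix(50, 2, 2), matrix(50, 2, 2),
                                    matrix(90, 2, 2), 160),
    class = "octapipe_segmentation_error"
  )
})

test_that("superficial slab spans [surface, surface + widen)", {
  bnd <- flat_boundaries()
  m <- make_plexus_mask(bnd, "superficial", widen_px = 15)
  col <- which(m$mask[, 1, 1])
  expect_equal(col, 51:65)  # 0-based bins 50..64
  expect_equal(sum(m$mask[, 1, 1]), 15)
  expect_equal(nrow(m$clipped), 0)
})

test_that("deep slab centers shift_px below the junction, shallow-resolved", {
  bnd <- flat_boundaries()
  m <- make_plexus_mask(bnd, "deep", widen_px = 14, shift_px = 12)
  col <- which(m$mask[, 1, 1]) - 1  # 0-based
  expect_equal(col, 85:98)  # junction 80 + 12 = 92 center; span 85..98
})

test_that("slabs clip at the depth limits and report the clipped columns", {
  bnd <- flat_boundaries(sup = 150, ipl = 152, rpe = 155, nd = 160)
  expect_message(
    m <- make_plexus_mask(bnd, "superficial", widen_px = 15),
    "clipped"
  )
  expect_equal(sum(m$mask[, 1, 1]), 10)  # bins 150..159
  expect_gt(nrow(m$clipped), 0)
})

test_that("a deep slab entirely below the RPE is rejected; widen warns", {
  bnd <- flat_boundaries()
  expect_error(
    make_plexus_mask(bnd, "deep", widen_px = 10, shift_px = 70),
    class = "octapipe_config_error"
  )
  expect_warning(make_plexus_mask(bnd, "superficial", widen_px = 5),
                 "recommended")
})

test_that("masking is an exact voxelwise product", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 32))
  oc <- compute_octa_volume(ph$volume)
  bnd <- flat_boundaries(ny = 32, nx = 48, sup = 0, ipl = 2, rpe = 190, nd = 192)
  ones <- suppressWarnings(make_plexus_mask(bnd, "superficial", widen_px = 192))
  expect_equal(apply_mask(oc, ones)$frames, oc$frames)
  zero <- ones
  zero$mask[] <- FALSE
  expect_equal(max(apply_mask(oc, zero)$frames), 0)
})

test_that("plexus masks separate superficial from deep lumen energy", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 33))
  oc <- compute_octa_volume(ph$volume)
  sv <- normalize_reflectance(to_log_structural(ph$volume))
  bnd <- detect_boundaries(sv)
  shift <- geometry_deep_shift(default_layer_stack(), 2)
  md <- make_plexus_mask(bnd, "deep", widen_px = 15, shift_px = shift)
  masked <- apply_mask(oc, md)
  deep_lum <- ph$truth$lumen_voxels$deep
  sup_lum <- ph$truth$lumen_voxels$superficial
  energy <- function(fr, idx) sum(fr[idx]^2)
  expect_gt(energy(masked$frames, deep_lum) / energy(oc$frames, deep_lum), 0.99)
  expect_lt(energy(masked$frames, sup_lum) / energy(oc$frames, sup_lum), 0.01)
})

test_that("auto deep shift lands near the geometric OPL offset", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 34))
  oc <- compute_octa_volume(ph$volume)
  sv <- normalize_reflectance(to_log_structural(ph$volume))
  bnd <- detect_boundaries(sv)
  m <- make_plexus_mask(bnd, "deep", widen_px = 15, shift_px = "auto", octa = oc)
  expect_lt(abs(m$shift_px - geometry_deep_shift(default_layer_stack(), 2)), 4)
})

test_that("boundary recovery stays below 1 px RMS across seeds", {
  errs <- vapply(1:5, function(s) {
    ph <- generate_phantom(tiny_phantom_spec(seed = 40 + s, noise_floor = 0))
    sv <- normalize_reflectance(to_log_structural(ph$volume))
    bnd <- detect_boundaries(sv)
    tr <- ph$truth$boundaries
    sqrt(mean(c(
      (bnd$superficial - tr$superficial)^2,
      (bnd$ipl_inl - tr$ipl_inl)^2,
      (bnd$rpe - tr$rpe)^2
    )))
  }, numeric(1))
  expect_lt(max(errs), 1)
})
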