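# Phantom specification: layered axial reflectivity, plexus vessel trees,
# speckle / flow-decorrelation model and degeneration schedules.

#' Default retinal layer stack for the phantom
#'
#' Ordered axial stack of retinal layers with physical thickness and mean
#' reflectivity (power scale, in `[0, 1]`). The ordering runs from the vitreous
#' downward: GCL (carrying the superficial plexus), IPL (intermediate plexus),
#' INL, OPL (deep plexus), ONL, a debris layer, and the RPE. Reflectivities
#' are chosen so the three reference interfaces a gradient-based segmentation
#' must find are the dominant axial gradients: the vitreous/GCL entry, the
#' bright-to-dark IPL/INL junction, and the debris/RPE step (the RPE is the
#' brightest layer).
#'
#' @return a tibble with columns `layer`, `thickness_um`, `reflectivity`.
#' @export
default_layer_stack <- function() {
  tibble(
    layer = c("GCL", "IPL", "INL", "OPL", "ONL", "debris", "RPE"),
    thickness_um = c(25, 45, 30, 25, 60, 15, 15),
    reflectivity = c(0.50, 0.55, 0.20, 0.40, 0.18, 0.22, 0.80)
  )
}

# Map from plexus name to the carrying layer.
plexus_layers <- c(superficial = "GCL", intermediate = "IPL", deep = "OPL")

polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
}

# Grow a random branching vessel network with the current RNG stream.
# Segments meet only at their end nodes (a branch event terminates the parent
# polyline and starts two children there), which keeps endpoint/junction
# ground truth a pure node-degree computation.
random_vessel_tree <- function(nx, ny, layer,
                               n_trunks = 3,
                               radius_px = 2,
                               total_length_px = 1500,
                               step_px = 3,
                               turn_sd = 0.25,
                               branch_prob = 0.05) {
  segments <- list()
  next_id <- 1L
  budget <- total_length_px
  clamp <- function(p) c(min(max(p[1], 1), nx), min(max(p[2], 1), ny))
  walkers <- lapply(seq_len(n_trunks), function(i) {
    list(pos = c(runif(1, nx * 0.05, nx * 0.95), runif(1, ny * 0.05, ny * 0.95)),
         theta = runif(1, 0, 2 * pi), radius = radius_px)
  })
  while (length(walkers) > 0 && budget > 0) {
    w <- walkers[[1]]
    walkers <- walkers[-1]
    pts <- matrix(w$pos, ncol = 2)
    repeat {
      w$theta <- w$theta + rnorm(1, 0, turn_sd)
      new_pos <- w$pos + step_px * c(cos(w$theta), sin(w$theta))
      out_of_field <- new_pos[1] < 1 || new_pos[1] > nx ||
        new_pos[2] < 1 || new_pos[2] > ny
      new_pos <- clamp(new_pos)
      pts <- rbind(pts, new_pos)
      w$pos <- new_pos
      budget <- budget - step_px
      if (out_of_field || budget <= 0) break
      if (runif(1) < branch_prob && length(walkers) < 64) {
        # branch: terminate this polyline here, spawn continuation + child
        dtheta <- runif(1, pi / 6, pi / 3) * sample(c(-1, 1), 1)
        walkers <- c(walkers, list(
          list(pos = w$pos, theta = w$theta, radius = w$radius),
          list(pos = w$pos, theta = w$theta + dtheta,
               radius = max(1, w$radius * 0.85))
        ))
        break
      }
    }
    if (nrow(pts) >= 2) {
      segments[[length(segments) + 1L]] <- list(
        id = next_id, xy = unname(pts), radius_px = max(1, w$radius)
      )
      next_id <- next_id + 1L
    }
  }
  structure(list(segments = segments, plexus_depth_layer = layer),
            class = "vessel_tree")
}

#' Generate the default three-plexus vessel trees
#'
#' Builds the superficial (GCL), intermediate (IPL) and deep (OPL) vascular
#' networks as random branching trees scaled to the lateral field of view. The
#' deep plexus is rendered as a dense fine-calibre capillary mesh, the
#' superficial plexus as fewer, larger vessels, matching the qualitative
#' appearance of rodent retinal plexuses.
#'
#' @param protocol a [scan_protocol()].
#' @param seed integer seed for the tree-growth randomness.
#' @return a named list of `vessel_tree` objects
#'   (`superficial`, `intermediate`, `deep`).
#' @export
default_vessel_trees <- function(protocol, seed = 1L) {
  nx <- protocol$n_alines_per_bscan
  ny <- protocol$n_positions
  area <- nx * ny
  with_seed(seed, {
    list(
      superficial = random_vessel_tree(
        nx, ny, "GCL", n_trunks = max(2, round(area / 6000)),
        radius_px = 2.5, total_length_px = 0.030 * area,
        branch_prob = 0.04
      ),
      intermediate = random_vessel_tree(
        nx, ny, "IPL", n_trunks = max(2, round(area / 5000)),
        radius_px = 1.5, total_length_px = 0.035 * area,
        branch_prob = 0.06
      ),
      deep = random_vessel_tree(
        nx, ny, "OPL", n_trunks = max(3, round(area / 3000)),
        radius_px = 1.2, total_length_px = 0.09 * area,
        branch_prob = 0.08
      )
    )
  })
}

# Smooth per-(position, aline) depth offset of the retina's top surface.
default_topography <- function(protocol, amplitude_px = 4, seed = 1L) {
  nx <- protocol$n_alines_per_bscan
  ny <- protocol$n_positions
  with_seed(seed, {
    fx <- runif(2, 0.5, 1.5)
    fy <- runif(2, 0.5, 1.5)
    ph <- runif(4, 0, 2 * pi)
    gx <- seq(0, 2 * pi, length.out = nx)
    gy <- seq(0, 2 * pi, length.out = ny)
    topo <- amplitude_px * 0.5 *
      (outer(sin(gy * fy[1] + ph[1]), sin(gx * fx[1] + ph[2])) +
         outer(cos(gy * fy[2] + ph[3]), cos(gx * fx[2] + ph[4])))
    topo
  })
}

#' Specify a synthetic retina phantom
#'
#' Assembles everything [generate_phantom()] needs to render a repeated-frame
#' complex OCT volume with ground truth: the scan protocol, the axial layer
#' stack, a smooth surface topography, one vessel tree per plexus, the speckle
#' model, per-plexus flow decorrelation, and the additive noise floor.
#'
#' The speckle model treats every voxel as a sum of sub-resolution
#' random-phase scatterers. With `speckle_model = "gaussian"` the
#' many-scatterer limit is drawn directly (circular complex Gaussian with
#' variance equal to the local reflectivity); with `"phasor"` a finite number
#' `scatterers_per_voxel` of unit phasors is summed. Flow contrast arises by
#' re-randomizing the phases of a fraction `flow_decorrelation` of each lumen
#' voxel's scatterers between repeats; static tissue keeps its scatterers, so
#' its inter-repeat decorrelation is exactly zero.
#'
#' @param protocol a [scan_protocol()].
#' @param layer_stack tibble as from [default_layer_stack()]; ordered top-down.
#' @param base_depth_um depth of the retinal surface below the image top.
#' @param topography_amplitude_px amplitude of the smooth surface topography.
#' @param vessel_trees named list of `vessel_tree` objects; defaults to
#'   [default_vessel_trees()]. Each tree's `plexus_depth_layer` must name a
#'   layer present in `layer_stack`.
#' @param flow_decorrelation named numeric in `[0, 1]`, one entry per tree:
#'   the fraction of lumen scatterers re-randomized between repeats.
#' @param blood_reflectivity reflectivity assigned to vessel lumen voxels.
#' @param choroid_reflectivity reflectivity of the tissue below the RPE.
#' @param scatterers_per_voxel scatterer count used by the `"phasor"` model.
#' @param speckle_model `"gaussian"` (default) or `"phasor"`.
#' @param noise_floor SD of the additive complex noise (per real/imaginary
#'   component) added independently to every voxel of every repeat.
#' @param seed master seed; trees and topography are derived from it so that
#'   equal `(spec, seed)` gives bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(protocol = scan_protocol(),
                         layer_stack = default_layer_stack(),
                         base_depth_um = 80,
                         topography_amplitude_px = 4,
                         vessel_trees = NULL,
                         flow_decorrelation = c(superficial = 1, intermediate = 1, deep = 1),
                         blood_reflectivity = 0.35,
                         choroid_reflectivity = 0.05,
                         scatterers_per_voxel = 10L,
                         speckle_model = c("gaussian", "phasor"),
                         noise_floor = 0.02,
                         seed = 1L) {
  speckle_model <- match.arg(speckle_model)
  stopifnot(inherits(protocol, "scan_protocol"))
  if (any(layer_stack$thickness_um <= 0)) {
    abort("layer thicknesses must be positive", class = "octapipe_config_error")
  }
  if (any(layer_stack$reflectivity < 0 | layer_stack$reflectivity > 1)) {
    abort("layer reflectivities must lie in [0, 1]", class = "octapipe_config_error")
  }
  vessel_trees <- vessel_trees %||% default_vessel_trees(protocol, seed = child_seed(seed, 11L))
  for (nm in names(vessel_trees)) {
    lyr <- vessel_trees[[nm]]$plexus_depth_layer
    if (!lyr %in% layer_stack$layer) {
      abort(sprintf("vessel tree '%s' references unknown layer '%s'", nm, lyr),
            class = "octapipe_config_error")
    }
  }
  if (is.null(names(flow_decorrelation)) ||
      !all(names(vessel_trees) %in% names(flow_decorrelation))) {
    abort("flow_decorrelation must be named, one entry per vessel tree",
          class = "octapipe_config_error")
  }
  if (any(flow_decorrelation < 0 | flow_decorrelation > 1)) {
    abort("flow_decorrelation must lie in [0, 1]", class = "octapipe_config_error")
  }
  structure(list(
    protocol = protocol,
    layer_stack = layer_stack,
    base_depth_um = base_depth_um,
    topography_amplitude_px = topography_amplitude_px,
    topography = default_topography(protocol, topography_amplitude_px,
                                    seed = child_seed(seed, 13L)),
    vessel_trees = vessel_trees,
    flow_decorrelation = flow_decorrelation,
    blood_reflectivity = blood_reflectivity,
    choroid_reflectivity = choroid_reflectivity,
    scatterers_per_voxel = as.integer(scatterers_per_voxel),
    speckle_model = speckle_model,
    noise_floor = noise_floor,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  print(x$protocol)
  cat(sprintf("  layers: %s\n", paste(x$layer_stack$layer, collapse = " > ")))
  cat(sprintf("  trees: %s; speckle: %s; noise_floor = %g; seed = %d\n",
              paste(names(x$vessel_trees), collapse = ", "),
              x$speckle_model, x$noise_floor, x$seed))
  invisible(x)
}

#' Degeneration schedule across timepoints
#'
#' Encodes the progressive structural and microvascular degeneration the
#' phantom emulates: outer nuclear layer (ONL) thinning, pruning of the deep
#' capillary plexus, and fragmentation of the surviving deep vessels. The
#' superficial plexus is left untouched at every timepoint, mirroring the
#' stability of the superficial network in degenerating retinas.
#'
#' @param timepoint_weeks numeric age labels (weeks), strictly increasing.
#' @param onl_thickness_scale per-timepoint multiplier of ONL thickness, in
#'   `[0, 1]` and non-increasing.
#' @param deep_prune_fraction per-timepoint fraction of deep-tree length
#'   removed, in `[0, 1]` and non-decreasing.
#' @param fragmentation_breaks_per_100px per-timepoint expected Poisson break
#'   count per 100 px of surviving deep vessel length, `>= 0`.
#' @return an object of class `degeneration_schedule`.
#' @export
degeneration_schedule <- function(timepoint_weeks,
                                  onl_thickness_scale,
                                  deep_prune_fraction,
                                  fragmentation_breaks_per_100px) {
  k <- length(timepoint_weeks)
  stopifnot(length(onl_thickness_scale) == k,
            length(deep_prune_fraction) == k,
            length(fragmentation_breaks_per_100px) == k)
  clamp01 <- function(v, nm) {
    if (any(v < 0 | v > 1)) {
      warn(sprintf("%s clamped into [0, 1]", nm))
      v <- pmin(pmax(v, 0), 1)
    }
    v
  }
  onl_thickness_scale <- clamp01(onl_thickness_scale, "onl_thickness_scale")
  deep_prune_fraction <- clamp01(deep_prune_fraction, "deep_prune_fraction")
  if (any(fragmentation_breaks_per_100px < 0)) {
    warn("fragmentation_breaks_per_100px clamped to >= 0")
    fragmentation_breaks_per_100px <- pmax(fragmentation_breaks_per_100px, 0)
  }
  if (is.unsorted(rev(onl_thickness_scale))) {
    abort("onl_thickness_scale must be non-increasing across timepoints",
          class = "octapipe_config_error")
  }
  if (is.unsorted(deep_prune_fraction)) {
    abort("deep_prune_fraction must be non-decreasing across timepoints",
          class = "octapipe_config_error")
  }
  structure(list(
    timepoint_weeks = timepoint_weeks,
    onl_thickness_scale = onl_thickness_scale,
    deep_prune_fraction = deep_prune_fraction,
    fragmentation_breaks_per_100px = fragmentation_breaks_per_100px
  ), class = "degeneration_schedule")
}

#' Default eight-timepoint degeneration time course
#'
#' Emulates the published RCS-rat phenomenology over eight imaging sessions
#' (weeks 3 to 12): the deep plexus is fully developed early, then progressive
#' pruning removes up to 70 percent of its length while fragmentation rises,
#' and the ONL thins towards disappearance; the superficial plexus never
#' changes.
#'
#' @return a [degeneration_schedule()].
#' @export
default_degeneration_schedule <- function() {
  degeneration_schedule(
    timepoint_weeks = c(3, 4, 5, 6, 7, 8, 10, 12),
    onl_thickness_scale = c(1, 0.90, 0.75, 0.60, 0.45, 0.30, 0.20, 0.15),
    deep_prune_fraction = c(0, 0, 0.10, 0.20, 0.30, 0.45, 0.60, 0.70),
    fragmentation_breaks_per_100px = c(0, 0, 0.5, 1, 2, 3, 4, 5)
  )
}

#' Schedule with no degeneration (wild-type control mode)
#'
#' Same timepoints as [default_degeneration_schedule()] but with no ONL
#' thinning, no pruning and no fragmentation; used as the null arm when
#' contrasting degenerating against stable time courses.
#'
#' @return a [degeneration_schedule()].
#' @export
control_degeneration_schedule <- function() {
  wk <- c(3, 4, 5, 6, 7, 8, 10, 12)
  degeneration_schedule(wk, rep(1, 8), rep(0, 8), rep(0, 8))
}

# split one polyline at given arclength positions, removing gap_px around each
split_segment_at <- function(seg, break_s, gap_px = 3, min_len = 2) {
  xy <- seg$xy
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (length(break_s) == 0) return(list(seg))
  keep <- matrix(c(0, total), ncol = 2)  # intervals to keep
  for (b in sort(break_s)) {
    lo <- b - gap_px / 2
    hi <- b + gap_px / 2
    new_keep <- NULL
    for (i in seq_len(nrow(keep))) {
      a <- keep[i, 1]; z <- keep[i, 2]
      if (hi <= a || lo >= z) {
        new_keep <- rbind(new_keep, c(a, z))
      } else {
        if (lo > a) new_keep <- rbind(new_keep, c(a, lo))
        if (hi < z) new_keep <- rbind(new_keep, c(hi, z))
      }
    }
    keep <- new_keep
    if (is.null(keep)) return(list())
  }
  # sample each kept interval back into a polyline
  interp_at <- function(sv) {
    i <- findInterval(sv, s, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), nrow(xy) - 1)
    w <- (sv - s[i]) / pmax(s[i + 1] - s[i], 1e-12)
    xy[i, , drop = FALSE] + w * (xy[i + 1, , drop = FALSE] - xy[i, , drop = FALSE])
  }
  out <- list()
  for (i in seq_len(nrow(keep))) {
    a <- keep[i, 1]; z <- keep[i, 2]
    if (z - a < min_len) next
    sv <- unique(sort(c(a, s[s > a & s < z], z)))
    piece <- interp_at(sv)
    out[[length(out) + 1L]] <- list(id = seg$id, xy = piece, radius_px = seg$radius_px)
  }
  out
}

#' Apply one timepoint of a degeneration schedule to a phantom spec
#'
#' Scales the ONL thickness, prunes whole deep-plexus segments until the
#' removed-length fraction reaches the scheduled value, and fragments the
#' surviving deep segments with Poisson-placed breaks (each break removes a
#' short gap of vessel). Superficial and intermediate trees are returned
#' unchanged.
#'
#' Pruning order and break positions are drawn from `seed` with a nested
#' construction: the removal order is a fixed permutation and breaks are
#' mark-thinned from a fixed maximal-rate Poisson process, so for a fixed
#' `seed` the vessel loss at a later (more degenerated) timepoint is a
#' superset of the loss at an earlier one whenever the schedule's prune
#' fraction and break rate are themselves monotone. This makes the rendered
#' deep vessel density non-increasing along the schedule for every seed.
#'
#' @param spec a [phantom_spec()].
#' @param schedule a [degeneration_schedule()].
#' @param timepoint_index index into the schedule.
#' @param seed integer seed for the degeneration randomness; use one seed per
#'   eye so that its timepoints share the same underlying loss process.
#' @param gap_px vessel length removed at each fragmentation break.
#' @return a modified `phantom_spec` with attribute `timepoint_weeks`.
#' @export
apply_degeneration <- function(spec, schedule, timepoint_index,
                               seed = spec$seed, gap_px = 3) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(schedule, "degeneration_schedule"))
  k <- length(schedule$timepoint_weeks)
  if (timepoint_index < 1 || timepoint_index > k) {
    abort("timepoint_index out of range", class = "octapipe_config_error")
  }
  onl_scale <- schedule$onl_thickness_scale[timepoint_index]
  prune <- schedule$deep_prune_fraction[timepoint_index]
  rate <- schedule$fragmentation_breaks_per_100px[timepoint_index]
  rate_max <- 10  # maximal thinning rate for the nested break construction

  out <- spec
  i_onl <- which(out$layer_stack$layer == "ONL")
  if (length(i_onl) == 1) {
    out$layer_stack$thickness_um[i_onl] <-
      out$layer_stack$thickness_um[i_onl] * onl_scale
  }

  deep <- out$vessel_trees$deep
  if (!is.null(deep) && length(deep$segments) > 0) {
    segs <- deep$segments
    lens <- vapply(segs, function(s) polyline_length(s$xy), numeric(1))
    total <- sum(lens)
    ord <- with_seed(child_seed(seed, 101L), sample.int(length(segs)))
    removed <- 0
    drop_idx <- integer(0)
    for (i in ord) {
      if (prune <= 0 || removed / total >= prune) break
      drop_idx <- c(drop_idx, i)
      removed <- removed + lens[i]
    }
    keep <- setdiff(seq_along(segs), drop_idx)
    segs <- segs[keep]
    # nested Poisson breaks: per-segment candidate set at rate_max, thinned by
    # uniform marks so that break sets grow with the scheduled rate
    new_segs <- list()
    for (s in segs) {
      L <- polyline_length(s$xy)
      cand <- with_seed(child_seed(seed, 211L, s$id), {
        n_cand <- rpois(1, L * rate_max / 100)
        list(pos = runif(n_cand, 0, L), mark = runif(n_cand, 0, rate_max))
      })
      br <- cand$pos[cand$mark < rate]
      new_segs <- c(new_segs, split_segment_at(s, br, gap_px = gap_px))
    }
    out$vessel_trees$deep$segments <- new_segs
  }
  attr(out, "timepoint_weeks") <- schedule$timepoint_weeks[timepoint_index]
  out
}
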