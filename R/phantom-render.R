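# Rendering of a phantom_spec into a repeated-frame complex OCT volume plus
# ground truth (boundaries, lumen voxels, en-face vessel masks, skeleton and
# density truth).

# Densely sample a polyline at ~0.4 px spacing.
sample_polyline <- function(xy, spacing = 0.4) {
  if (nrow(xy) < 2) return(xy)
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  sv <- seq(0, total, by = spacing)
  i <- findInterval(sv, s, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), nrow(xy) - 1)
  w <- (sv - s[i]) / pmax(s[i + 1] - s[i], 1e-12)
  xy[i, , drop = FALSE] + w * (xy[i + 1, , drop = FALSE] - xy[i, , drop = FALSE])
}

# Rasterize a vessel tree into an en-face mask [ny, nx] and a radius map.
rasterize_tree <- function(tree, nx, ny) {
  mask <- matrix(FALSE, ny, nx)
  rad <- matrix(0, ny, nx)
  for (seg in tree$segments) {
    pts <- sample_polyline(seg$xy)
    r <- seg$radius_px
    ri <- ceiling(r)
    offs <- expand.grid(dx = -ri:ri, dy = -ri:ri)
    offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 1e-9, , drop = FALSE]
    cx <- round(pts[, 1])
    cy <- round(pts[, 2])
    for (k in seq_len(nrow(offs))) {
      px <- cx + offs$dx[k]
      py <- cy + offs$dy[k]
      ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
      if (!any(ok)) next
      idx <- cbind(py[ok], px[ok])
      mask[idx] <- TRUE
      rad[idx] <- pmax(rad[idx], r)
    }
  }
  list(mask = mask, radius = rad)
}

# Node-degree skeleton truth from tree segments: endpoints are degree-1 nodes,
# branch points degree >= 3; length is total polyline arclength.
tree_skeleton_truth <- function(tree) {
  segs <- tree$segments
  if (length(segs) == 0) {
    return(list(n_endpoints = 0L, n_branches = 0L, total_length_px = 0))
  }
  key <- function(p) paste(round(p[1], 2), round(p[2], 2))
  ends <- unlist(lapply(segs, function(s) {
    c(key(s$xy[1, ]), key(s$xy[nrow(s$xy), ]))
  }))
  deg <- table(ends)
  list(
    n_endpoints = sum(deg == 1),
    n_branches = sum(deg >= 3),
    total_length_px = sum(vapply(segs, function(s) polyline_length(s$xy), numeric(1)))
  )
}

# Brute-force per-window density of a logical en-face mask (non-overlapping
# windows anchored at (1,1); partial edge windows dropped).
window_density_bruteforce <- function(mask, window_px = 20L) {
  nwr <- nrow(mask) %/% window_px
  nwc <- ncol(mask) %/% window_px
  out <- matrix(NA_real_, nwr, nwc)
  for (i in seq_len(nwr)) {
    for (j in seq_len(nwc)) {
      rows <- ((i - 1) * window_px + 1):(i * window_px)
      cols <- ((j - 1) * window_px + 1):(j * window_px)
      out[i, j] <- sum(mask[rows, cols]) / window_px^2
    }
  }
  out
}

# Integer layer boundaries (first voxel row of each layer) for a spec, before
# the per-column topography shift. Returns a named integer vector of length
# n_layers + 1 (last entry = first row below the RPE).
layer_boundaries_px <- function(spec) {
  z <- spec$protocol$pixel_size_z_um
  base <- round(spec$base_depth_um / z)
  th <- spec$layer_stack$thickness_um / z
  b <- base + c(0, cumsum(th))
  b <- as.integer(round(b))
  names(b) <- c(spec$layer_stack$layer, "below")
  b
}

draw_speckle <- function(n, refl, model, n_scatter) {
  if (model == "gaussian") {
    cpp_draw_speckle(rep_len(refl, n))
  } else {
    acc <- complex(real = numeric(n), imaginary = numeric(n))
    for (s in seq_len(n_scatter)) {
      ph <- runif(n, 0, 2 * pi)
      acc <- acc + complex(real = cos(ph), imaginary = sin(ph))
    }
    acc * sqrt(refl / n_scatter)
  }
}

#' Render a phantom into a repeated-frame complex OCT volume
#'
#' Draws a static speckle field from the layered reflectivity profile (shifted
#' per column by the surface topography), embeds each plexus' vessel lumens at
#' its carrying layer's depth, and produces `n_repeats` complex frames per
#' slow position. Between repeats, static tissue keeps its speckle realization
#' exactly; lumen voxels have a fraction `flow_decorrelation` of their
#' scatterer content re-randomized, which is what the complex-difference
#' angiogram later detects. Independent complex noise of SD `noise_floor` is
#' added to every voxel of every repeat.
#'
#' @param spec a [phantom_spec()], possibly degenerated with
#'   [apply_degeneration()].
#' @return a list with elements `volume` (an `oct_volume`: complex array
#'   `[n_depth, n_alines, n_repeats, n_positions]`) and `truth` (a
#'   `phantom_truth` with boundary maps, per-plexus en-face vessel masks,
#'   lumen voxel indices, skeleton truth and window-density truth).
#' @export
#' @examples
#' p <- scan_protocol(n_alines_per_bscan = 32, n_positions = 16,
#'                    n_repeats = 2, n_spectral = 128, pixel_size_z_um = 6)
#' ph <- generate_phantom(phantom_spec(p, noise_floor = 0, seed = 7))
#' dim(ph$volume$frames)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  proto <- spec$protocol
  nd <- proto$n_depth
  nx <- proto$n_alines_per_bscan
  ny <- proto$n_positions
  nrep <- proto$n_repeats

  b <- layer_boundaries_px(spec)
  if (b[["below"]] >= nd) {
    abort(sprintf(
      "retina (%d px deep, ending at row %d) does not fit in n_depth = %d; increase n_depth or pixel_size_z_um",
      b[["below"]] - b[[1]], b[["below"]], nd), class = "octapipe_config_error")
  }

  # axial reflectivity profile (vitreous above, choroid-like tail below)
  profile <- rep(0, nd)
  refl <- spec$layer_stack$reflectivity
  for (i in seq_along(refl)) {
    rows <- (b[i]):(b[i + 1] - 1L)
    profile[rows + 1L] <- refl[i]  # boundaries are 0-based depth bins
  }
  tail_rows <- (b[["below"]] + 1L):nd
  profile[tail_rows] <- spec$choroid_reflectivity %||% 0.05

  shift <- round(spec$topography)  # [ny, nx] integer column shifts

  # reflectivity volume [nd, nx, ny] via grouped integer shifts of the profile
  refl_vol <- matrix(0, nd, nx * ny)
  u_shift <- sort(unique(as.vector(shift)))
  for (s in u_shift) {
    sel <- which(t(shift) == s)  # in aline-major order matching [nx, ny]
    src <- seq_len(nd) - s
    prof_s <- ifelse(src >= 1 & src <= nd, profile[pmin(pmax(src, 1L), nd)], 0)
    refl_vol[, sel] <- prof_s
  }
  dim(refl_vol) <- c(nd, nx, ny)

  # ground-truth boundary maps (0-based depth bins, matching rendered volume)
  truth_boundaries <- list(
    superficial = b[["GCL"]] + shift,
    ipl_inl = b[["INL"]] + shift,
    rpe = b[["RPE"]] + shift
  )

  # plexus lumen voxels
  plexus_info <- list()
  lumen <- list()
  for (nm in names(spec$vessel_trees)) {
    tree <- spec$vessel_trees[[nm]]
    ras <- rasterize_tree(tree, nx, ny)
    lyr <- tree$plexus_depth_layer
    i_lyr <- match(lyr, spec$layer_stack$layer)
    center0 <- as.integer(round((b[[i_lyr]] + b[[i_lyr + 1]] - 1) / 2))
    cols <- which(ras$mask)  # [ny, nx] order: position-major
    if (length(cols) > 0) {
      py <- ((cols - 1L) %% ny) + 1L
      px <- ((cols - 1L) %/% ny) + 1L
      rz <- pmax(1L, as.integer(round(ras$radius[cols])))
      reps <- 2L * rz + 1L
      ctr <- center0 + shift[cbind(py, px)] + 1L  # 1-based center row
      d0 <- rep(ctr, reps) + sequence(reps) - rep(rz, reps) - 1L
      pxr <- rep(px, reps)
      pyr <- rep(py, reps)
      ok <- d0 >= 1L & d0 <= nd
      lin <- d0[ok] + (pxr[ok] - 1L) * nd + (pyr[ok] - 1L) * nd * nx
      lumen[[nm]] <- unique(lin)
    } else {
      lumen[[nm]] <- integer(0)
    }
    plexus_info[[nm]] <- list(mask = ras$mask, radius = ras$radius,
                              center_bin = center0)
  }
  all_lumen <- as.integer(unlist(lumen, use.names = FALSE))
  refl_vol[all_lumen] <- spec$blood_reflectivity

  # speckle: one static realization; lumen voxels mix static + fresh parts
  n_vox <- length(refl_vol)
  frames <- with_seed(child_seed(spec$seed, 29L), {
    u0 <- draw_speckle(n_vox, as.vector(refl_vol), spec$speckle_model,
                       spec$scatterers_per_voxel)
    d_l <- numeric(0)
    if (length(all_lumen) > 0) {
      # per-tree decorrelation
      d_vec <- numeric(n_vox)
      for (nm in names(lumen)) d_vec[lumen[[nm]]] <- spec$flow_decorrelation[[nm]]
      d_l <- d_vec[all_lumen]
      u0[all_lumen] <- sqrt(1 - d_l) * u0[all_lumen]
    }
    if (spec$speckle_model == "gaussian") {
      cpp_render_frames(u0, c(nd, nx, ny), nrep, all_lumen,
                        as.vector(refl_vol)[all_lumen] * d_l,
                        spec$noise_floor)
    } else {
      fr <- array(complex(real = 0, imaginary = 0), dim = c(nd, nx, nrep, ny))
      for (j in seq_len(nrep)) {
        frame <- u0
        if (length(all_lumen) > 0) {
          fresh <- draw_speckle(length(all_lumen),
                                as.vector(refl_vol)[all_lumen] * d_l,
                                spec$speckle_model, spec$scatterers_per_voxel)
          frame[all_lumen] <- frame[all_lumen] + fresh
        }
        if (spec$noise_floor > 0) {
          frame <- frame + complex(real = rnorm(n_vox, 0, spec$noise_floor),
                                   imaginary = rnorm(n_vox, 0, spec$noise_floor))
        }
        fr[, , j, ] <- array(frame, dim = c(nd, nx, ny))
      }
      fr
    }
  })

  volume <- new_oct_volume(frames, proto, seed = spec$seed)

  truth <- structure(list(
    boundaries = truth_boundaries,
    plexus_masks = lapply(plexus_info, `[[`, "mask"),
    plexus_center_bin = vapply(plexus_info, `[[`, integer(1), "center_bin"),
    lumen_voxels = lumen,
    skeleton = dplyr::bind_rows(lapply(names(spec$vessel_trees), function(nm) {
      st <- tree_skeleton_truth(spec$vessel_trees[[nm]])
      tibble(plexus = nm, n_endpoints = st$n_endpoints,
             n_branches = st$n_branches, total_length_px = st$total_length_px)
    })),
    density = lapply(plexus_info, function(pi) {
      window_density_bruteforce(pi$mask, 20L)
    }),
    density_window_px = 20L
  ), class = "phantom_truth")

  list(volume = volume, truth = truth)
}

# Constructor for the complex repeated-frame volume container.
new_oct_volume <- function(frames, protocol, seed = NULL, provenance = NULL) {
  stopifnot(length(dim(frames)) == 4)
  structure(list(frames = frames, protocol = protocol, seed = seed,
                 provenance = provenance),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<oct_volume> %d depth x %d alines x %d repeats x %d positions (complex)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Extract the repeated complex frames at one slow position
#'
#' @param volume an `oct_volume`.
#' @param position slow-axis index.
#' @return a complex array `[n_depth, n_alines, n_repeats]`.
#' @export
oct_frames_at <- function(volume, position) {
  stopifnot(inherits(volume, "oct_volume"))
  volume$frames[, , , position, drop = FALSE][, , , 1]
}
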