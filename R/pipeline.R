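# Configuration and pipeline orchestration: simulate -> reconstruct -> octa
# -> segment -> project -> quantify -> stats, per (subject, eye, timepoint).

#' Default run configuration
#'
#' Nested configuration for a full simulated longitudinal run. Every key can
#' be overridden from a YAML file via [read_run_config()]; unknown keys are
#' rejected.
#'
#' Segmentation note: `deep_shift_px = "geometry"` derives the deep-slab
#' shift from the configured phantom layer stack (the distance from the
#' IPL/INL junction to the middle of the OPL), which is the simulation-study
#' analogue of tuning the shift manually per dataset; a fixed integer or
#' `"auto"` (OCTA-driven) may be given instead.
#'
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "octapipe-run",
    phantom = list(
      n_alines_per_bscan = 128L, n_positions = 128L, n_repeats = 5L,
      n_spectral = 512L, n_depth = 256L,
      pixel_size_xy_um = 5, pixel_size_z_um = 2,
      noise_floor = 0.02, speckle_model = "gaussian",
      topography_amplitude_px = 4, blood_reflectivity = 0.35,
      flow_decorrelation = 1
    ),
    simulate = list(
      n_subjects = 6L, n_eyes = 2L, schedule = "default",
      emit_spectra = FALSE
    ),
    reconstruction = list(normalize = TRUE, min_snr_db = 15),
    angiography = list(phase_align = TRUE),
    segmentation = list(
      widen_px = 15L, deep_shift_px = "geometry", smoothness = 0.5,
      min_retina_px = 30L
    ),
    quantification = list(window_px = 20L, threshold = "otsu",
                          threshold_value = NULL),
    stats = list(average_eyes = FALSE, alpha = 0.05)
  ), class = "run_config")
}

check_known_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0) {
    abort(sprintf("unknown config key(s): %s",
                  paste0(path, extra, collapse = ", ")),
          class = "octapipe_config_error")
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) {
        abort(sprintf("config key %s%s must be a mapping", path, nm),
              class = "octapipe_config_error")
      }
      check_known_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Loads the YAML file, validates every key against [default_run_config()]
#' (unknown keys are an error), and merges it over the defaults.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_run_config()
  check_known_keys(cfg, ref)
  structure(merge_config(unclass(ref), cfg), class = "run_config")
}

config_protocol <- function(cfg) {
  ph <- cfg$phantom
  scan_protocol(
    n_alines_per_bscan = ph$n_alines_per_bscan,
    n_positions = ph$n_positions,
    n_repeats = ph$n_repeats,
    n_spectral = ph$n_spectral,
    n_depth = ph$n_depth,
    pixel_size_xy_um = ph$pixel_size_xy_um,
    pixel_size_z_um = ph$pixel_size_z_um
  )
}

config_schedule <- function(cfg) {
  switch(cfg$simulate$schedule,
    default = default_degeneration_schedule(),
    control = control_degeneration_schedule(),
    abort(sprintf("unknown schedule '%s'", cfg$simulate$schedule),
          class = "octapipe_config_error")
  )
}

#' Deep-slab shift implied by a phantom layer stack
#'
#' Distance, in depth bins, from the IPL/INL junction to the centre of the
#' OPL (where the deep plexus lives): the geometric analogue of the manual
#' per-dataset shift tuning used on real data.
#'
#' @param layer_stack tibble as from [default_layer_stack()].
#' @param pixel_size_z_um axial micrometres per pixel.
#' @return integer shift in depth bins.
#' @export
geometry_deep_shift <- function(layer_stack = default_layer_stack(),
                                pixel_size_z_um = 2) {
  inl <- layer_stack$thickness_um[layer_stack$layer == "INL"]
  opl <- layer_stack$thickness_um[layer_stack$layer == "OPL"]
  as.integer(round((inl + opl / 2) / pixel_size_z_um))
}

resolve_deep_shift <- function(cfg) {
  s <- cfg$segmentation$deep_shift_px
  if (identical(s, "geometry")) {
    geometry_deep_shift(default_layer_stack(), cfg$phantom$pixel_size_z_um)
  } else {
    s
  }
}

#' Run one volume through the full image-computation chain
#'
#' From a repeated-frame complex volume to per-plexus vessel metrics:
#' structural image + normalization, quality score, OCTA computation, layer
#' segmentation, slab masking, en-face maximum intensity projection, and
#' quantification.
#'
#' @param volume an `oct_volume`.
#' @param cfg a `run_config` (defaults used where absent).
#' @return a list with `metrics` (two-row tibble, superficial and deep),
#'   `quality`, `boundaries`, and the two en-face maps.
#' @export
process_volume <- function(volume, cfg = default_run_config()) {
  sv <- to_log_structural(volume)
  quality <- assess_quality(sv, min_snr_db = cfg$reconstruction$min_snr_db)
  if (isTRUE(cfg$reconstruction$normalize)) sv <- normalize_reflectance(sv)
  octa <- compute_octa_volume(volume, phase_align = cfg$angiography$phase_align)
  bnd <- detect_boundaries(sv, smoothness = cfg$segmentation$smoothness,
                           min_retina_px = cfg$segmentation$min_retina_px)
  shift <- resolve_deep_shift(cfg)
  rows <- list()
  maps <- list()
  for (plexus in c("superficial", "deep")) {
    m <- make_plexus_mask(bnd, plexus, widen_px = cfg$segmentation$widen_px,
                          shift_px = if (plexus == "deep") shift else 0L,
                          octa = octa)
    masked <- apply_mask(octa, m)
    ef <- enface_project(masked, "mip")
    q <- quantify_enface(ef, window_px = cfg$quantification$window_px,
                         threshold_method = cfg$quantification$threshold,
                         threshold_value = cfg$quantification$threshold_value)
    rows[[plexus]] <- dplyr::mutate(q, plexus = plexus, .before = 1)
    maps[[plexus]] <- ef
  }
  list(metrics = dplyr::bind_rows(rows), quality = quality,
       boundaries = bnd, enface = maps)
}

#' Simulate a longitudinal cohort and quantify every eye at every timepoint
#'
#' For each (subject, eye) a base phantom is grown from a child seed of the
#' master seed; for each scheduled timepoint the degeneration is applied
#' (eye-level loss process, so vessel loss accumulates consistently within an
#' eye) and the full pipeline of [process_volume()] produces the per-plexus
#' vessel metrics. Identical `(config, seed)` reproduces identical metrics.
#'
#' @param cfg a `run_config`.
#' @param seed master seed (defaults to `cfg$seed`).
#' @param timepoint_subset optional integer indices to restrict timepoints.
#' @param progress emit one message per eye.
#' @return a tibble with one row per (subject, eye, timepoint, plexus).
#' @export
simulate_cohort <- function(cfg = default_run_config(), seed = cfg$seed,
                            timepoint_subset = NULL, progress = FALSE) {
  proto <- config_protocol(cfg)
  schedule <- config_schedule(cfg)
  tps <- timepoint_subset %||% seq_along(schedule$timepoint_weeks)
  out <- list()
  fd <- cfg$phantom$flow_decorrelation
  for (s in seq_len(cfg$simulate$n_subjects)) {
    for (e in seq_len(cfg$simulate$n_eyes)) {
      eye_seed <- child_seed(seed, s, e)
      base <- phantom_spec(
        proto,
        topography_amplitude_px = cfg$phantom$topography_amplitude_px,
        flow_decorrelation = c(superficial = fd, intermediate = fd, deep = fd),
        blood_reflectivity = cfg$phantom$blood_reflectivity,
        speckle_model = cfg$phantom$speckle_model,
        noise_floor = cfg$phantom$noise_floor,
        seed = eye_seed
      )
      deg_seed <- child_seed(seed, s, e, 7L)
      if (progress) inform(sprintf("subject %d eye %d", s, e))
      for (t in tps) {
        spec_t <- apply_degeneration(base, schedule, t, seed = deg_seed)
        spec_t$seed <- child_seed(seed, s, e, 100L + t)
        ph <- generate_phantom(spec_t)
        vol <- ph$volume
        if (isTRUE(cfg$simulate$emit_spectra)) {
          vol <- reconstruct_volume(synthesize_spectra(vol))
        }
        res <- process_volume(vol, cfg)
        out[[length(out) + 1L]] <- dplyr::mutate(
          res$metrics,
          subject = s, eye = e,
          timepoint_weeks = schedule$timepoint_weeks[t],
          snr_db = res$quality$score_db,
          .before = 1
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Longitudinal statistics for a cohort metrics table
#'
#' Runs, per plexus and metric, the Greenhouse-Geisser-corrected
#' repeated-measures ANOVA, Tukey post hoc comparisons, and the linear age
#' trend.
#'
#' @param metrics wide per-eye metrics from [simulate_cohort()].
#' @param cfg a `run_config` (for `average_eyes`).
#' @return a list with tibbles `anova`, `trend`, and a named list `tukey`.
#' @export
cohort_stats <- function(metrics, cfg = default_run_config()) {
  long <- metrics_long(metrics)
  combos <- expand.grid(
    plexus = unique(long$plexus),
    metric = c("density_mean", "endpoints_per_area", "branches_per_area",
               "length_px"),
    stringsAsFactors = FALSE
  )
  anova_rows <- list()
  trend_rows <- list()
  tukey_out <- list()
  for (i in seq_len(nrow(combos))) {
    pl <- combos$plexus[i]
    me <- combos$metric[i]
    a <- rm_anova_gg(long, me, pl, average_eyes = cfg$stats$average_eyes)
    anova_rows[[i]] <- dplyr::mutate(tidy(a), plexus = pl, metric = me,
                                     .before = 1)
    tr <- linear_trend(long, me, pl)
    trend_rows[[i]] <- dplyr::mutate(tr, plexus = pl, metric = me, .before = 1)
    tukey_out[[paste(pl, me, sep = ".")]] <-
      tukey_posthoc(long, me, pl, average_eyes = cfg$stats$average_eyes)
  }
  list(anova = dplyr::bind_rows(anova_rows),
       trend = dplyr::bind_rows(trend_rows),
       tukey = tukey_out)
}

#' Run the full pipeline and write its artifacts
#'
#' Simulates the configured cohort, quantifies it, runs the longitudinal
#' statistics, and writes the metrics CSV, the statistics CSVs and a JSON run
#' manifest (config, seed, artifact paths and MD5 checksums) under
#' `cfg$out_dir`. Rerunning with an identical config reproduces byte-identical
#' metric CSVs.
#'
#' @param cfg a `run_config`.
#' @param progress emit per-eye progress messages.
#' @return (invisibly) the manifest as a list.
#' @export
run_pipeline <- function(cfg = default_run_config(), progress = FALSE) {
  if (cfg$phantom$n_repeats < 2) {
    abort("stage octa: n_repeats must be >= 2 to form sequential pairs",
          class = "octapipe_stage_error")
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)),
            class = "octapipe_stage_error", parent = e)
    })
  }
  metrics <- stage("simulate+quantify", simulate_cohort(cfg, progress = progress))
  metrics_path <- file.path(out_dir, "metrics.csv")
  write.csv(metrics, metrics_path, row.names = FALSE)
  stats <- stage("stats", cohort_stats(metrics, cfg))
  anova_path <- file.path(out_dir, "stats_anova.csv")
  trend_path <- file.path(out_dir, "stats_trend.csv")
  write.csv(stats$anova, anova_path, row.names = FALSE)
  write.csv(stats$trend, trend_path, row.names = FALSE)
  paths <- c(metrics = metrics_path, anova = anova_path, trend = trend_path)
  manifest <- list(
    format_version = format_version,
    seed = cfg$seed,
    config = unclass(cfg),
    artifacts = as.list(paths),
    checksums = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
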