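# Longitudinal statistics for vessel-metric time courses: one-way
# repeated-measures ANOVA with Greenhouse-Geisser correction, Tukey post hoc
# comparisons, and linear age trends.

# Reshape a long time-course table into a complete-case wide matrix
# (units x timepoints), eyes-as-units by default.
timecourse_wide <- function(table, metric, plexus = NULL, average_eyes = FALSE) {
  stopifnot(all(c("subject", "timepoint_weeks", "metric", "value") %in% names(table)))
  d <- dplyr::filter(table, .data$metric == !!metric)
  if (!is.null(plexus)) d <- dplyr::filter(d, .data$plexus == !!plexus)
  if (nrow(d) == 0) abort("no rows for this metric/plexus", class = "octapipe_data_error")
  if (!"eye" %in% names(d)) d$eye <- 1L
  if (average_eyes) {
    d <- d |>
      dplyr::group_by(.data$subject, .data$timepoint_weeks) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(unit = as.character(.data$subject))
  } else {
    d <- dplyr::mutate(d, unit = paste(.data$subject, .data$eye, sep = "/"))
  }
  dup <- d |>
    dplyr::count(.data$unit, .data$timepoint_weeks) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate (unit, timepoint) records", class = "octapipe_data_error")
  }
  wide <- tidyr::pivot_wider(
    d[, c("unit", "timepoint_weeks", "value")],
    names_from = "timepoint_weeks", values_from = "value"
  )
  complete <- complete.cases(wide)
  if (any(!complete)) {
    warn(sprintf("%d incomplete unit(s) dropped (missing timepoints)", sum(!complete)))
    wide <- wide[complete, , drop = FALSE]
  }
  Y <- as.matrix(wide[, -1, drop = FALSE])
  rownames(Y) <- wide$unit
  Y[, order(as.numeric(colnames(Y))), drop = FALSE]
}

# Greenhouse-Geisser epsilon from the sample covariance of repeated measures.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  S <- cov(Y)
  cm <- colMeans(S)
  Sstar <- S - outer(cm, rep(1, k)) - outer(rep(1, k), cm) + mean(S)
  num <- sum(diag(Sstar))^2
  den <- (k - 1) * sum(Sstar^2)
  eps <- if (den <= 0) 1 else num / den
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Tests the within-unit effect of timepoint on one metric. The F statistic
#' comes from the standard univariate repeated-measures decomposition
#' (`aov` with a unit error stratum); the Greenhouse-Geisser epsilon is
#' estimated from the sample covariance of the repeated measures and used to
#' shrink both degrees of freedom before computing the corrected p-value.
#' Units are subject-eye combinations by default (`average_eyes = TRUE`
#' averages the two eyes of a subject first). Units missing any timepoint are
#' dropped with a warning.
#'
#' @param table long time-course tibble with columns `subject`, `eye`
#'   (optional), `timepoint_weeks`, `plexus`, `metric`, `value`.
#' @param metric metric name to test.
#' @param plexus optional plexus filter.
#' @param average_eyes treat the rat, not the eye, as the unit.
#' @return an `octa_rm_anova` object; see [tidy()] and [glance()] methods.
#' @export
rm_anova_gg <- function(table, metric, plexus = NULL, average_eyes = FALSE) {
  Y <- timecourse_wide(table, metric, plexus, average_eyes)
  n <- nrow(Y)
  k <- ncol(Y)
  if (n < 3) abort("need at least 3 complete units", class = "octapipe_data_error")
  if (k < 2) abort("need at least 2 timepoints", class = "octapipe_data_error")
  long <- data.frame(
    value = as.vector(Y),
    unit = factor(rep(rownames(Y), times = k)),
    timepoint = factor(rep(colnames(Y), each = n),
                       levels = colnames(Y))
  )
  fit <- aov(value ~ timepoint + Error(unit), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  F_val <- tab["timepoint", "F value"]
  df1 <- tab["timepoint", "Df"]
  df2 <- tab["Residuals", "Df"]
  p_unc <- tab["timepoint", "Pr(>F)"]
  eps <- gg_epsilon(Y)
  p_gg <- pf(F_val, eps * df1, eps * df2, lower.tail = FALSE)
  structure(list(
    statistic = F_val, df1 = df1, df2 = df2, epsilon = eps,
    p_uncorrected = p_unc, p_gg = p_gg,
    n_units = n, k_timepoints = k,
    metric = metric, plexus = plexus %||% NA_character_,
    data_wide = Y
  ), class = "octa_rm_anova")
}

#' @export
print.octa_rm_anova <- function(x, ...) {
  cat(sprintf(
    "RM-ANOVA (%s%s): F(%d, %d) = %.3f, GG epsilon = %.3f, p = %.4g (GG-corrected %.4g)\n",
    x$metric, if (!is.na(x$plexus)) paste0(", ", x$plexus) else "",
    x$df1, x$df2, x$statistic, x$epsilon, x$p_uncorrected, x$p_gg))
  invisible(x)
}

#' @rdname rm_anova_gg
#' @param x an `octa_rm_anova` object.
#' @param ... unused.
#' @export
tidy.octa_rm_anova <- function(x, ...) {
  tibble(
    term = "timepoint", statistic = x$statistic,
    df1 = x$df1, df2 = x$df2, epsilon = x$epsilon,
    p.value = x$p_uncorrected, p.value.gg = x$p_gg
  )
}

#' @rdname rm_anova_gg
#' @export
glance.octa_rm_anova <- function(x, ...) {
  tibble(n_units = x$n_units, k_timepoints = x$k_timepoints,
         statistic = x$statistic, epsilon = x$epsilon, p.value.gg = x$p_gg)
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Tukey post hoc comparisons between timepoints
#'
#' All pairwise timepoint comparisons with studentized-range (Tukey HSD)
#' adjustment, using the classical repeated-measures error term (the
#' unit-by-timepoint interaction mean square from the additive
#' `unit + timepoint` fit). Stars mark `p < 0.05` (*), `< 0.01` (**) and
#' `< 0.001` (***).
#'
#' @inheritParams rm_anova_gg
#' @return a tibble with one row per timepoint pair: `pair`, `diff`,
#'   `conf.low`, `conf.high`, `p.adj`, `stars`.
#' @export
tukey_posthoc <- function(table, metric, plexus = NULL, average_eyes = FALSE) {
  Y <- timecourse_wide(table, metric, plexus, average_eyes)
  n <- nrow(Y)
  k <- ncol(Y)
  if (n < 3) abort("need at least 3 complete units", class = "octapipe_data_error")
  long <- data.frame(
    value = as.vector(Y),
    unit = factor(rep(rownames(Y), times = k)),
    timepoint = factor(rep(colnames(Y), each = n), levels = colnames(Y))
  )
  fit <- aov(value ~ unit + timepoint, data = long)
  tk <- TukeyHSD(fit, "timepoint")$timepoint
  tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    conf.low = tk[, "lwr"],
    conf.high = tk[, "upr"],
    p.adj = tk[, "p adj"],
    stars = significance_stars(tk[, "p adj"])
  )
}

#' Linear trend of a metric over age
#'
#' Ordinary least squares of the metric on age in weeks, pooling eyes (every
#' record is one observation), with the two-sided slope test. Used to
#' contrast monotone degeneration time courses against stable (control)
#' ones.
#'
#' @inheritParams rm_anova_gg
#' @return a one-row tibble: `slope`, `intercept`, `r.squared`, `p.value`,
#'   `n_obs`.
#' @export
linear_trend <- function(table, metric, plexus = NULL) {
  d <- dplyr::filter(table, .data$metric == !!metric)
  if (!is.null(plexus)) d <- dplyr::filter(d, .data$plexus == !!plexus)
  if (nrow(d) == 0) abort("no rows for this metric/plexus", class = "octapipe_data_error")
  x <- d$timepoint_weeks
  if (length(unique(x)) < 3) {
    abort("need at least 3 distinct timepoints for a trend",
          class = "octapipe_data_error")
  }
  fit <- lm(value ~ timepoint_weeks, data = d)
  sm <- summary(fit)
  tibble(
    slope = coef(fit)[["timepoint_weeks"]],
    intercept = coef(fit)[["(Intercept)"]],
    r.squared = sm$r.squared,
    p.value = sm$coefficients["timepoint_weeks", "Pr(>|t|)"],
    n_obs = nrow(d)
  )
}

#' Pivot a per-eye metrics table to long format
#'
#' Turns the wide per-(subject, eye, timepoint, plexus) metric columns
#' produced by [simulate_cohort()] into the long `metric`/`value` records the
#' statistical tests consume.
#'
#' @param metrics tibble with columns `subject`, `eye`, `timepoint_weeks`,
#'   `plexus`, and metric columns `density_mean`, `endpoints_per_area`,
#'   `branches_per_area`, `length_px`.
#' @return a long tibble with columns `subject`, `eye`, `timepoint_weeks`,
#'   `plexus`, `metric`, `value`.
#' @export
metrics_long <- function(metrics) {
  tidyr::pivot_longer(
    metrics,
    cols = dplyr::any_of(c("density_mean", "endpoints_per_area",
                           "branches_per_area", "length_px", "n_pieces")),
    names_to = "metric", values_to = "value"
  )
}
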