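# ggplot2 displays for en-face maps, density maps and metric time courses.

map_to_df <- function(m) {
  data.frame(
    position = rep(seq_len(nrow(m)), times = ncol(m)),
    aline = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Display an en-face map
#'
#' @param object an `enface_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enface_map <- function(object, ...) {
  df <- map_to_df(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$aline, .data$position,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "A-line", y = "position",
                  fill = attr(object, "source") %||% "value") +
    ggplot2::theme_minimal()
}

#' Display a windowed vessel density map in pseudo-colour
#'
#' Blue-to-red ramp from low to high density, the conventional display for
#' vessel area density maps.
#'
#' @param object a `density_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.density_map <- function(object, ...) {
  df <- map_to_df(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$aline, .data$position,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("blue", "cyan", "yellow", "red"),
                                  limits = c(0, max(object, 0.5))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "window column", y = "window row", fill = "density") +
    ggplot2::theme_minimal()
}

#' Time-course plot of a vessel metric
#'
#' Per-eye observations with the across-eye mean and standard deviation per
#' timepoint, faceted by plexus.
#'
#' @param metrics wide metrics tibble from [simulate_cohort()].
#' @param metric metric column to plot (e.g. `"density_mean"`).
#' @return a ggplot.
#' @export
plot_time_course <- function(metrics, metric = "density_mean") {
  stopifnot(metric %in% names(metrics))
  d <- dplyr::rename(metrics, value = dplyr::all_of(metric))
  s <- d |>
    dplyr::group_by(.data$plexus, .data$timepoint_weeks) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$timepoint_weeks, .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = s, ggplot2::aes(y = .data$mean),
                       colour = "red3") +
    ggplot2::geom_errorbar(
      data = s,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.3, colour = "red3"
    ) +
    ggplot2::facet_wrap(~plexus, scales = "free_y") +
    ggplot2::labs(x = "age (weeks)", y = metric) +
    ggplot2::theme_bw()
}
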