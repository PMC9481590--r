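#' @export
autoplot.travel_time_grid <- function(object, max_minutes = NULL, ...) {
  df <- as_tibble.geo_grid(object)
  df$value[is.infinite(df$value)] <- NA
  if (!is.null(max_minutes)) df$value <- pmin(df$value, max_minutes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey30", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "minutes", x = "easting (m)", y = "northing (m)",
                  title = "Travel time to nearest facility") +
    ggplot2::theme_minimal()
}

#' Coverage curves per dataset
#'
#' Relative accessibility coverage against travel-time threshold, one
#' line per dataset, for a single admin unit (default: whole region).
#'
#' @param cov A `coverage_table`.
#' @param level,unit Which unit to plot.
#' @return A ggplot object.
#' @export
plot_coverage_curves <- function(cov, level = 0, unit = "region") {
  df <- dplyr::filter(tibble::as_tibble(cov), .data$admin_level == level,
                      .data$admin_id == unit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold_min,
                                   y = .data$coverage_pct,
                                   colour = .data$dataset)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "travel-time threshold (min)", y = "coverage (%)",
                  colour = "dataset") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pairwise_diff_matrix <- function(object, ...) {
  df <- tidy.pairwise_diff_matrix(object)
  full <- dplyr::bind_rows(df, dplyr::rename(df, dataset_a = "dataset_b",
                                             dataset_b = "dataset_a"))
  ggplot2::ggplot(full, ggplot2::aes(x = .data$dataset_a, y = .data$dataset_b,
                                     fill = .data$diff_pp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$diff_pp))) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(title = sprintf("Coverage difference (pp) at %g min",
                                  attr(object, "threshold_min")),
                  x = NULL, y = NULL, fill = "pp") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.unit_diff_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$area_km2, y = .data$mean_diff_pp,
                               size = .data$mean_total_pop,
                               colour = .data$pop_quartile)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "unit area (km², log)",
                  y = "mean pairwise coverage difference (pp)",
                  size = "mean population", colour = "pop quartile") +
    ggplot2::theme_minimal()
}
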