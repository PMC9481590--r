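#' Accessibility coverage statistics (zonal statistics)
#'
#' Aggregates classified population points into absolute and relative
#' coverage per dataset, administrative unit and travel-time threshold:
#' the population able to reach its nearest facility within each
#' threshold. The denominator excludes population on barriers and
#' out-of-region points but keeps unreachable-on-land population, so an
#' island of people cut off by rivers lowers coverage rather than
#' disappearing from it. A whole-region (level 0) row is always emitted.
#'
#' @param points Classified points from [classify_points()].
#' @param thresholds Increasing travel-time thresholds in minutes.
#' @param levels Admin levels to aggregate over, besides level 0.
#' @return A `coverage_table` tibble: `dataset`, `admin_level`,
#'   `admin_id`, `threshold_min`, `pop_covered`, `pop_total`,
#'   `coverage_pct` (`NA` where a unit has no non-barrier population),
#'   `pop_on_barrier`, `pop_unreachable`. `coverage_pct` is full
#'   precision; round only at serialization.
#' @examples
#' pts <- tibble::tibble(x = 1:3, y = 1, count = c(10, 30, 60),
#'                       dataset = "demo", status = "finite",
#'                       travel_time_min = c(20, 50, 200))
#' coverage_stats(pts, thresholds = 60, levels = integer())
#' @export
coverage_stats <- function(points, thresholds = c(30, 60, 90, 120, 150, 180),
                           levels = c(1, 2)) {
  if (is.unsorted(thresholds, strictly = TRUE) || any(thresholds <= 0))
    stop("thresholds must be strictly increasing and positive", call. = FALSE)
  if (!"status" %in% names(points))
    stop("points are not classified; run classify_points() first", call. = FALSE)
  if (!nrow(points)) {
    warning("empty point set; empty coverage table", call. = FALSE)
    return(empty_coverage_table())
  }
  pts <- dplyr::filter(tibble::as_tibble(points), .data$status != "out_of_region")

  one_level <- function(df, level, id_col) {
    grp <- if (is.null(id_col)) dplyr::group_by(df, .data$dataset) else
      dplyr::group_by(df, .data$dataset,
                      admin_id = .data[[id_col]], .drop = TRUE)
    base <- dplyr::summarise(
      grp,
      pop_total = sum(.data$count[.data$status %in% c("finite", "unreachable")]),
      pop_on_barrier = sum(.data$count[.data$status == "barrier"]),
      pop_unreachable = sum(.data$count[.data$status == "unreachable"]),
      covered_list = list(vapply(
        thresholds,
        function(th) sum(.data$count[.data$status == "finite" &
                                       .data$travel_time_min <= th]),
        numeric(1))),
      .groups = "drop")
    if (is.null(id_col)) base$admin_id <- "region"
    base$admin_level <- level
    tidyr::unnest_longer(
      dplyr::mutate(base, threshold_min = list(thresholds)),
      c("covered_list", "threshold_min")) |>
      dplyr::rename(pop_covered = "covered_list")
  }

  parts <- list(one_level(pts, 0L, NULL))
  for (lv in levels) {
    col <- paste0("admin", lv, "_id")
    if (!col %in% names(pts))
      stop("points lack ", col, "; classify_points() with level ", lv,
           call. = FALSE)
    parts[[length(parts) + 1L]] <-
      one_level(dplyr::filter(pts, !is.na(.data[[col]])), as.integer(lv), col)
  }
  out <- dplyr::bind_rows(parts) |>
    dplyr::mutate(coverage_pct = ifelse(.data$pop_total > 0,
                                        100 * .data$pop_covered / .data$pop_total,
                                        NA_real_)) |>
    dplyr::select("dataset", "admin_level", "admin_id", "threshold_min",
                  "pop_covered", "pop_total", "coverage_pct",
                  "pop_on_barrier", "pop_unreachable") |>
    dplyr::arrange(.data$dataset, .data$admin_level, .data$admin_id,
                   .data$threshold_min)
  structure(out, class = c("coverage_table", class(out)))
}

empty_coverage_table <- function() {
  structure(tibble::tibble(
    dataset = character(), admin_level = integer(), admin_id = character(),
    threshold_min = numeric(), pop_covered = numeric(), pop_total = numeric(),
    coverage_pct = numeric(), pop_on_barrier = numeric(),
    pop_unreachable = numeric()),
    class = c("coverage_table", "tbl_df", "tbl", "data.frame"))
}

#' Population falling on barriers, per dataset
#'
#' Absolute and relative counts of population whose point falls on an
#' impassable cell; these people are excluded from coverage statistics
#' (and not reallocated). The share is relative to barrier plus on-land
#' population; out-of-region points enter neither side.
#'
#' @param points Classified points from [classify_points()].
#' @return A tibble: `dataset`, `pop_on_barrier`, `pct_on_barrier`.
#' @export
barrier_report <- function(points) {
  tibble::as_tibble(points) |>
    dplyr::filter(.data$status != "out_of_region") |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      pop_on_barrier = sum(.data$count[.data$status == "barrier"]),
      pct_on_barrier = {
        b <- sum(.data$count[.data$status == "barrier"])
        nb <- sum(.data$count[.data$status != "barrier"])
        if (b + nb > 0) 100 * b / (b + nb) else 0
      },
      .groups = "drop")
}

#' Serialize a coverage table
#'
#' Writes `coverage.csv` with the documented header; percentages are
#' rounded to one decimal here and only here.
#'
#' @param cov A `coverage_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  out <- dplyr::mutate(tibble::as_tibble(cov),
                       coverage_pct = round(.data$coverage_pct, 1))
  readr::write_csv(out, path, na = "")
  invisible(path)
}
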