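#' Pairwise coverage-difference matrix
#'
#' Differences in accessibility coverage between datasets at one
#' threshold for one unit, in percentage points: entry (A, B) =
#' |coverage_pct_A - coverage_pct_B|. Absolute differences (the 0-70+ pp
#' magnitudes comparisons in this field report), so the matrix is
#' symmetric with a zero diagonal.
#'
#' @param cov A `coverage_table`.
#' @param threshold Travel-time threshold (minutes).
#' @param level Admin level of the unit (0 = whole region).
#' @param unit Admin id (default the whole-region row).
#' @return A `pairwise_diff_matrix` (numeric matrix with dataset
#'   dimnames; attribute `threshold_min`).
#' @export
pairwise_diff <- function(cov, threshold, level = 0, unit = "region") {
  rows <- dplyr::filter(tibble::as_tibble(cov),
                        .data$threshold_min == threshold,
                        .data$admin_level == level, .data$admin_id == unit)
  all_ds <- sort(unique(cov$dataset))
  missing_ds <- setdiff(all_ds, rows$dataset)
  if (length(missing_ds))
    stop("no coverage row for dataset(s) ", paste(missing_ds, collapse = ", "),
         " at (", unit, ", ", threshold, " min)", call. = FALSE)
  pct <- stats::setNames(rows$coverage_pct[match(all_ds, rows$dataset)], all_ds)
  m <- abs(outer(pct, pct, "-"))
  dimnames(m) <- list(all_ds, all_ds)
  structure(m, class = c("pairwise_diff_matrix", "matrix", "array"),
            threshold_min = threshold)
}

#' @export
print.pairwise_diff_matrix <- function(x, ...) {
  cat("Pairwise coverage difference (pp) at",
      attr(x, "threshold_min"), "min\n")
  m <- round(unclass(x), 1)
  attr(m, "threshold_min") <- NULL
  print(m)
  invisible(x)
}

#' Tidy a pairwise difference matrix
#'
#' @param x A `pairwise_diff_matrix`.
#' @param ... Unused.
#' @return A tibble `threshold_min`, `dataset_a`, `dataset_b`, `diff_pp`
#'   (unordered pairs, a < b).
#' @export
tidy.pairwise_diff_matrix <- function(x, ...) {
  ds <- rownames(x)
  pairs <- utils::combn(ds, 2)
  tibble::tibble(threshold_min = attr(x, "threshold_min"),
                 dataset_a = pairs[1, ], dataset_b = pairs[2, ],
                 diff_pp = x[t(pairs)])
}

#' Per-unit average coverage difference across datasets
#'
#' For every admin unit at one level and threshold: the mean over all
#' unordered dataset pairs of the absolute coverage difference (pp),
#' joined with unit area and the across-dataset mean total population,
#' binned into population quartiles. This is the per-unit disagreement
#' map statistic; large, sparsely populated units are where gridded
#' population products disagree most.
#'
#' @param cov A `coverage_table` holding >= 2 datasets.
#' @param threshold Travel-time threshold (minutes).
#' @param level Admin level (1 or 2).
#' @param admin_units Admin-unit table supplying `area_km2` per id.
#' @return A `unit_diff_summary` tibble: `admin_id`, `level`,
#'   `mean_diff_pp`, `area_km2`, `mean_total_pop`, `pop_quartile`.
#' @export
average_unit_diff <- function(cov, threshold, level, admin_units = NULL) {
  df <- dplyr::filter(tibble::as_tibble(cov),
                      .data$threshold_min == threshold,
                      .data$admin_level == level)
  if (dplyr::n_distinct(df$dataset) < 2)
    stop("average_unit_diff needs at least two datasets", call. = FALSE)
  out <- df |>
    dplyr::group_by(admin_id = .data$admin_id) |>
    dplyr::summarise(
      mean_diff_pp = {
        p <- .data$coverage_pct[!is.na(.data$coverage_pct)]
        if (length(p) >= 2) mean(abs(outer(p, p, "-"))[upper.tri(diag(length(p)))])
        else NA_real_
      },
      mean_total_pop = mean(.data$pop_total),
      .groups = "drop") |>
    dplyr::mutate(level = as.integer(level), .after = "admin_id")
  if (!is.null(admin_units)) {
    areas <- tibble::as_tibble(admin_units)[c("id", "area_km2")]
    out <- dplyr::left_join(out, areas, by = c(admin_id = "id"))
  } else {
    out$area_km2 <- NA_real_
  }
  qs <- stats::quantile(out$mean_total_pop, probs = seq(0, 1, 0.25), na.rm = TRUE)
  out$pop_quartile <- if (length(unique(qs)) == 5)
    cut(out$mean_total_pop, qs, labels = paste0("Q", 1:4), include.lowest = TRUE)
  else factor(rep("Q1", nrow(out)), levels = paste0("Q", 1:4))
  structure(out, class = c("unit_diff_summary", class(out)),
            threshold_min = threshold)
}

#' Association between census-unit size and dataset disagreement
#'
#' Spearman rank correlation between unit area and the mean pairwise
#' coverage difference, plus per-population-quartile group means. A
#' positive coefficient says larger units disagree more — the signature
#' of coarse census units interacting with different redistribution
#' schemes.
#'
#' @param unit_diff A `unit_diff_summary` from [average_unit_diff()], or
#'   any data frame with columns `mean_diff_pp`, `area_km2`,
#'   `mean_total_pop` — e.g. summaries for coarse (level-1) and fine
#'   (level-2) census units stacked with [dplyr::bind_rows()], the
#'   natural way to study census-release coarseness. Needs >= 5 units.
#'   Population quartiles are (re)computed over the supplied units.
#' @return A `size_association` object; see [tidy.size_association()]
#'   and [glance.size_association()].
#' @export
size_association <- function(unit_diff) {
  df <- tibble::as_tibble(unit_diff)
  need <- c("mean_diff_pp", "area_km2", "mean_total_pop")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("size_association needs columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- dplyr::filter(df, !is.na(.data$mean_diff_pp), !is.na(.data$area_km2))
  if (nrow(df) < 5)
    stop("size_association needs at least 5 units with defined differences",
         call. = FALSE)
  qs <- stats::quantile(df$mean_total_pop, probs = seq(0, 1, 0.25))
  df$pop_quartile <- if (length(unique(qs)) == 5)
    cut(df$mean_total_pop, qs, labels = paste0("Q", 1:4), include.lowest = TRUE)
  else factor(rep("Q1", nrow(df)), levels = paste0("Q", 1:4))
  degenerate <- stats::sd(df$mean_diff_pp) == 0 || stats::sd(df$area_km2) == 0
  rho <- if (degenerate) NA_real_ else
    stats::cor(df$area_km2, df$mean_diff_pp, method = "spearman")
  group_means <- df |>
    dplyr::group_by(pop_quartile = .data$pop_quartile) |>
    dplyr::summarise(mean_diff_pp = mean(.data$mean_diff_pp),
                     mean_area_km2 = mean(.data$area_km2),
                     n_units = dplyr::n(), .groups = "drop")
  structure(list(rho = rho, n_units = nrow(df), degenerate = degenerate,
                 group_means = group_means, data = df),
            class = "size_association")
}

#' @export
print.size_association <- function(x, ...) {
  cat("Unit size vs coverage disagreement\n")
  if (x$degenerate) cat("  degenerate input: correlation undefined\n")
  else cat(sprintf("  Spearman rho = %.3f over %d units\n", x$rho, x$n_units))
  print(x$group_means)
  invisible(x)
}

#' Tidy a size-association fit
#'
#' @param x A `size_association`.
#' @param ... Unused.
#' @return One row per population quartile with group means.
#' @export
tidy.size_association <- function(x, ...) x$group_means

#' One-row summary of a size-association fit
#'
#' @param x A `size_association`.
#' @param ... Unused.
#' @return A tibble with `rho`, `n_units`, `degenerate`.
#' @export
glance.size_association <- function(x, ...) {
  tibble::tibble(rho = x$rho, n_units = x$n_units, degenerate = x$degenerate)
}
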