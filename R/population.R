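#' Construct a population grid
#'
#' @param values Matrix of nonnegative person counts; `NA` = nodata.
#' @param spec A [grid_spec()]; the resolution may differ from the
#'   friction grid (population is never resampled, see [to_points()]).
#' @param name Dataset name, unique within a run.
#' @return A `population_grid`.
#' @export
population_grid <- function(values, spec, name) {
  if (any(values < 0, na.rm = TRUE))
    stop("population counts must be nonnegative", call. = FALSE)
  g <- geo_grid(values, spec, name = name)
  class(g) <- c("population_grid", class(g))
  g
}

# Assign points to admin units at one level: first containing polygon in
# stable id order wins (the documented on-edge tie rule).
assign_units <- function(x, y, admin_units, level) {
  units <- admin_units[admin_units$level == level, , drop = FALSE]
  units <- units[order(units$id), , drop = FALSE]
  out <- rep(NA_character_, length(x))
  for (j in seq_len(nrow(units))) {
    todo <- is.na(out)
    if (!any(todo)) break
    ring <- units$geometry[[j]]
    hit <- sp::point.in.polygon(x[todo], y[todo], ring[, 1], ring[, 2]) > 0
    out[which(todo)[hit]] <- units$id[j]
  }
  out
}

#' Harmonize a population raster with exact mass preservation
#'
#' Clips the raster to the study region and then restores, per level-2
#' administrative unit, the unit total of the original raster: every cell
#' in a unit is multiplied by (original unit total / post-clip unit
#' total), so each unit's mass matches the original exactly while the
#' within-unit spatial pattern is preserved. A unit whose post-clip total
#' is zero but whose original total is positive gets the original total
#' spread uniformly over its land cells, with a warning (the fallback
#' real gridded products use).
#'
#' All grids in a run share one projected CRS; a raster in a different
#' CRS is refused rather than resampled.
#'
#' @param pop A `population_grid`.
#' @param admin_units Admin-unit table (`id`, `level`, `geometry`, ...)
#'   containing level-2 units covering the region.
#' @param region Optional polygon [geo_features()] (or single ring
#'   matrix); cells whose centroid falls outside are clipped to `NA`.
#' @param water_mask Optional logical matrix; water cells are excluded
#'   from the uniform-respread fallback.
#' @param original_totals Optional named vector of per-unit totals to
#'   restore; defaults to the totals of `pop` before clipping.
#' @return A `population_grid`; attribute `scale_factors` is a tibble of
#'   per-unit factors (logged for provenance).
#' @export
harmonize <- function(pop, admin_units, region = NULL, water_mask = NULL,
                      original_totals = NULL) {
  stopifnot(inherits(pop, "population_grid"))
  spec <- pop$spec
  idx <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  ctr <- cell_centroid(spec, idx$row, idx$col)
  unit <- assign_units(ctr[, 1], ctr[, 2], admin_units, level = 2)
  unit_mat <- matrix(unit, spec$n_rows, spec$n_cols)

  vals <- pop$values
  if (is.null(original_totals)) {
    tot <- tapply(as.vector(vals), unit, sum, na.rm = TRUE)
    original_totals <- stats::setNames(as.numeric(tot), names(tot))
  }

  if (!is.null(region)) {
    ring <- if (inherits(region, "geo_features")) {
      check_crs(region, spec)
      region$geometry[[1]]
    } else region
    inside <- sp::point.in.polygon(ctr[, 1], ctr[, 2], ring[, 1], ring[, 2]) > 0
    if (!any(inside))
      stop("region is disjoint from the population raster", call. = FALSE)
    vals[matrix(!inside, spec$n_rows, spec$n_cols)] <- NA_real_
  }

  ids <- names(original_totals)
  factors <- tibble::tibble(admin_id = ids, original = as.numeric(original_totals),
                            post = NA_real_, factor = NA_real_)
  land <- if (is.null(water_mask)) matrix(TRUE, spec$n_rows, spec$n_cols) else !water_mask
  for (k in seq_along(ids)) {
    in_unit <- unit_mat == ids[k] & !is.na(unit_mat)
    post <- sum(vals[in_unit], na.rm = TRUE)
    factors$post[k] <- post
    orig <- factors$original[k]
    if (post > 0) {
      f <- orig / post
      sel <- in_unit & !is.na(vals)
      vals[sel] <- vals[sel] * f
      factors$factor[k] <- f
    } else if (orig > 0) {
      sel <- in_unit & land
      # clipped-away cells come back as land so the mass has a home
      if (!any(sel)) sel <- in_unit
      vals[sel] <- orig / sum(sel)
      factors$factor[k] <- NA_real_
      warning("unit ", ids[k], ": all population lost in processing; ",
              "respread ", orig, " uniformly over ", sum(sel), " land cells",
              call. = FALSE)
    } else {
      factors$factor[k] <- 1
    }
  }
  out <- population_grid(vals, spec, name = pop$name)
  structure(out, scale_factors = factors)
}

#' Convert a population grid to centroid points
#'
#' One point per cell with positive count, at the cell centroid — the
#' resampling-free representation used for extraction: coarse datasets
#' keep their native resolution and are sampled, never resampled, against
#' the travel-time surface.
#'
#' @param pop A `population_grid`.
#' @return A tibble (`x`, `y`, `count`, `dataset`) with the grid's CRS id
#'   in attribute `crs_id`. Total count equals the grid total.
#' @export
to_points <- function(pop) {
  stopifnot(inherits(pop, "population_grid"))
  spec <- pop$spec
  keep <- which(!is.na(pop$values) & pop$values > 0, arr.ind = TRUE)
  if (!nrow(keep)) warning("population grid '", pop$name,
                           "' has no positive cells", call. = FALSE)
  ctr <- cell_centroid(spec, keep[, 1], keep[, 2])
  out <- tibble::tibble(x = ctr[, 1], y = ctr[, 2],
                        count = pop$values[keep],
                        dataset = pop$name %||% "population")
  structure(out, crs_id = spec$crs_id)
}

#' Annotate population points with travel time and admin units
#'
#' Each point gets the travel-time value of its containing cell and an
#' admin id per requested level. The classification is total: every
#' point ends up in exactly one of `finite` (with minutes), `barrier`,
#' `unreachable`, or `out_of_region` (outside the grid or outside every
#' admin polygon).
#'
#' @param points Tibble from [to_points()] (columns `x`, `y`, `count`,
#'   `dataset`).
#' @param tt A `travel_time_grid`.
#' @param admin_units Admin-unit table with the requested levels.
#' @param levels Admin levels to annotate (subset of 1:2).
#' @return The input tibble plus `travel_time_min`, `status`, and
#'   `admin<level>_id` columns.
#' @export
classify_points <- function(points, tt, admin_units, levels = c(1, 2)) {
  stopifnot(inherits(tt, "travel_time_grid"))
  pcrs <- attr(points, "crs_id", exact = TRUE)
  if (!is.null(pcrs) && !identical(pcrs, tt$spec$crs_id))
    stop("CRS mismatch: points are '", pcrs, "', travel-time grid is '",
         tt$spec$crs_id, "'", call. = FALSE)
  pts <- tibble::as_tibble(points)
  cells <- point_to_cell(tt$spec, pts$x, pts$y)
  on_grid <- !is.na(cells$row)
  ttv <- rep(NA_real_, nrow(pts))
  ttv[on_grid] <- tt$values[cbind(cells$row[on_grid], cells$col[on_grid])]
  status <- rep("out_of_region", nrow(pts))
  status[on_grid & is.na(ttv)] <- "barrier"
  status[on_grid & is.infinite(ttv)] <- "unreachable"
  status[on_grid & is.finite(ttv)] <- "finite"

  in_any <- rep(FALSE, nrow(pts))
  for (lv in levels) {
    ids <- assign_units(pts$x, pts$y, admin_units, level = lv)
    pts[[paste0("admin", lv, "_id")]] <- ids
    in_any <- in_any | !is.na(ids)
  }
  if (length(levels)) status[!in_any] <- "out_of_region"
  pts$travel_time_min <- ifelse(status == "finite", ttv, NA_real_)
  pts$status <- status
  structure(pts, crs_id = tt$spec$crs_id)
}
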