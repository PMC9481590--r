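#' @title Friction-surface construction
#' @description Turns landcover, road and waterbody layers into a merged
#'   class grid under the bridge-priority rule (road > barrier >
#'   landcover) and converts it to a per-cell crossing-time surface via a
#'   travel scenario.
#' @name friction
NULL

# All cells whose closed square a segment touches (Liang-Barsky clip per
# candidate cell, closed interval so a corner graze counts). Coordinates
# in map units; returns integer matrix (row, col).
segment_cells <- function(spec, x0, y0, x1, y1) {
  cs <- spec$cell_size
  # candidate window: bbox of the segment, clamped to the lattice
  cmin <- max(1L, floor((min(x0, x1) - spec$origin_x) / cs) + 1)
  cmax <- min(spec$n_cols, floor((max(x0, x1) - spec$origin_x) / cs) + 1)
  rmin <- max(1L, floor((spec$origin_y - max(y0, y1)) / cs) + 1)
  rmax <- min(spec$n_rows, floor((spec$origin_y - min(y0, y1)) / cs) + 1)
  if (cmin > cmax || rmin > rmax) return(cbind(row = integer(), col = integer()))
  cand <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  xl <- spec$origin_x + (cand$col - 1) * cs
  xr <- xl + cs
  yt <- spec$origin_y - (cand$row - 1) * cs
  yb <- yt - cs
  dx <- x1 - x0
  dy <- y1 - y0
  t0 <- rep(0, nrow(cand))
  t1 <- rep(1, nrow(cand))
  ok <- rep(TRUE, nrow(cand))
  clip <- function(p, q) {
    # p scalar slope component, q vector of distances to the edge
    if (p == 0) {
      ok <<- ok & q >= 0
    } else if (p < 0) {
      t0 <<- pmax(t0, q / p)
    } else {
      t1 <<- pmin(t1, q / p)
    }
  }
  clip(-dx, x0 - xl)
  clip(dx, xr - x0)
  clip(-dy, y0 - yb)
  clip(dy, yt - y0)
  keep <- ok & t0 <= t1 + 1e-12
  as.matrix(cand[keep, c("row", "col"), drop = FALSE])
}

line_cells <- function(spec, coords) {
  segs <- lapply(seq_len(nrow(coords) - 1), function(i)
    segment_cells(spec, coords[i, 1], coords[i, 2],
                  coords[i + 1, 1], coords[i + 1, 2]))
  unique(do.call(rbind, segs))
}

check_crs <- function(features, spec) {
  if (!identical(feature_crs(features), spec$crs_id))
    stop("CRS mismatch: features are in '", feature_crs(features),
         "', grid is '", spec$crs_id, "'; reproject upstream, never silently",
         call. = FALSE)
  invisible(TRUE)
}

#' Rasterize class-coded lines (all-touched)
#'
#' Every cell whose (closed) square the line touches receives the line's
#' class code. Where lines of different class touch the same cell, the
#' class with the higher scenario speed wins — the connectivity-preserving
#' choice for crossing roads.
#'
#' @param lines A [geo_features()] line collection with a `class_code`
#'   column.
#' @param spec Target [grid_spec()]; must share the lines' CRS.
#' @param scenario A `scenario_table` supplying the speeds used to break
#'   class conflicts.
#' @return An integer matrix (`NA` = no line) with attribute
#'   `n_conflicts`, the number of cells where classes competed.
#' @export
rasterize_lines <- function(lines, spec, scenario = default_scenario()) {
  check_crs(lines, spec)
  out <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  if (!nrow(lines)) return(structure(out, n_conflicts = 0L))
  if (!"class_code" %in% names(lines))
    stop("line features need a class_code column", call. = FALSE)
  speed <- stats::setNames(scenario$speed_kmh, scenario$class_code)
  n_conflicts <- 0L
  for (j in seq_len(nrow(lines))) {
    cls <- as.integer(lines$class_code[j])
    cells <- line_cells(spec, lines$geometry[[j]])
    if (!nrow(cells)) next
    idx <- cbind(cells[, "row"], cells[, "col"])
    cur <- out[idx]
    sp_new <- speed[as.character(cls)]
    sp_cur <- speed[as.character(cur)]
    contested <- !is.na(cur) & cur != cls
    n_conflicts <- n_conflicts + sum(contested)
    take <- is.na(cur) |
      (contested & (is.na(sp_cur) | (!is.na(sp_new) & sp_new > sp_cur)))
    out[idx[take, , drop = FALSE]] <- cls
  }
  structure(out, n_conflicts = n_conflicts)
}

#' Rasterize movement barriers
#'
#' River lines use the all-touched rule so narrow rivers stay continuous
#' barriers; water polygons mark a cell only when its centroid is covered,
#' so lake edges are not inflated.
#'
#' @param river_lines A line [geo_features()] collection (may be empty or
#'   `NULL`).
#' @param water_polygons A polygon [geo_features()] collection (may be
#'   empty or `NULL`).
#' @param spec Target [grid_spec()].
#' @return A logical barrier-mask matrix.
#' @export
rasterize_barriers <- function(river_lines, water_polygons, spec) {
  mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
  if (!is.null(river_lines) && nrow(river_lines)) {
    check_crs(river_lines, spec)
    for (j in seq_len(nrow(river_lines))) {
      cells <- line_cells(spec, river_lines$geometry[[j]])
      if (nrow(cells)) mask[cbind(cells[, "row"], cells[, "col"])] <- TRUE
    }
  }
  if (!is.null(water_polygons) && nrow(water_polygons)) {
    check_crs(water_polygons, spec)
    for (j in seq_len(nrow(water_polygons))) {
      ring <- water_polygons$geometry[[j]]
      cs <- spec$cell_size
      cmin <- max(1L, floor((min(ring[, 1]) - spec$origin_x) / cs) + 1)
      cmax <- min(spec$n_cols, floor((max(ring[, 1]) - spec$origin_x) / cs) + 1)
      rmin <- max(1L, floor((spec$origin_y - max(ring[, 2])) / cs) + 1)
      rmax <- min(spec$n_rows, floor((spec$origin_y - min(ring[, 2])) / cs) + 1)
      if (cmin > cmax || rmin > rmax) next
      cand <- expand.grid(row = rmin:rmax, col = cmin:cmax)
      ctr <- cell_centroid(spec, cand$row, cand$col)
      inside <- sp::point.in.polygon(ctr[, 1], ctr[, 2], ring[, 1], ring[, 2]) > 0
      mask[cbind(cand$row[inside], cand$col[inside])] <- TRUE
    }
  }
  mask
}

#' Merge landcover, roads and barriers into one class grid
#'
#' Priority is road > barrier > landcover: a road cell keeps its road
#' class even over water (the bridge rule), remaining barrier cells get
#' the barrier class, and everything else keeps its landcover class.
#'
#' @param landcover A [geo_grid()] of landcover class codes; must be
#'   complete (no `NA`) wherever neither road nor barrier supplies a
#'   class.
#' @param road_classes Integer matrix from [rasterize_lines()], or `NULL`.
#' @param barrier_mask Logical matrix from [rasterize_barriers()], or
#'   `NULL`.
#' @param barrier_class Class code written into barrier cells.
#' @return A `merged_class_grid`: list of `classes` (integer matrix),
#'   `provenance` (`"road"`/`"barrier"`/`"landcover"` matrix) and `spec`.
#' @export
merge_layers <- function(landcover, road_classes = NULL, barrier_mask = NULL,
                         barrier_class = 200L) {
  spec <- landcover$spec
  classes <- matrix(as.integer(landcover$values), spec$n_rows, spec$n_cols)
  prov <- matrix("landcover", spec$n_rows, spec$n_cols)
  if (!is.null(barrier_mask)) {
    stopifnot(identical(dim(barrier_mask), dim(classes)))
    classes[barrier_mask] <- barrier_class
    prov[barrier_mask] <- "barrier"
  }
  if (!is.null(road_classes)) {
    stopifnot(identical(dim(unclass(road_classes)), dim(classes)))
    has_road <- !is.na(road_classes)
    classes[has_road] <- road_classes[has_road]
    prov[has_road] <- "road"
  }
  if (anyNA(classes)) {
    n <- sum(is.na(classes))
    stop(n, " cell(s) have no class in any layer; the landcover layer ",
         "must be complete", call. = FALSE)
  }
  structure(list(classes = classes, provenance = prov, spec = spec),
            class = "merged_class_grid")
}

#' @export
print.merged_class_grid <- function(x, ...) {
  cat(sprintf("<merged_class_grid> %s\n", format(x$spec)))
  print(table(provenance = x$provenance))
  invisible(x)
}

#' Complete a travel scenario against the classes actually present
#'
#' Classes present in the merged grid but absent from the scenario are
#' filled from a fallback table of average class speeds; the filled
#' classes are logged. A class in neither table is an error.
#'
#' @param scenario A `scenario_table`.
#' @param classes_present Integer vector of class codes in the merged
#'   grid.
#' @param fallback Fallback table (`class_code`, `label`, `mode`,
#'   `speed_kmh`), by default [default_fallback()].
#' @return A complete `scenario_table`; attribute `filled` lists the
#'   class codes taken from the fallback.
#' @export
resolve_scenario <- function(scenario, classes_present,
                             fallback = default_fallback()) {
  classes_present <- unique(as.integer(classes_present))
  missing_cls <- setdiff(classes_present, scenario$class_code)
  if (!length(missing_cls)) return(structure(scenario, filled = integer()))
  from_fb <- fallback[fallback$class_code %in% missing_cls, , drop = FALSE]
  still <- setdiff(missing_cls, from_fb$class_code)
  if (length(still))
    stop("class(es) with neither scenario nor fallback speed: ",
         paste(still, collapse = ", "), call. = FALSE)
  message("scenario: filled class(es) ",
          paste(from_fb$class_code, collapse = ", "),
          " from average fallback speeds")
  out <- as_scenario_table(dplyr::bind_rows(scenario, from_fb))
  structure(out, filled = from_fb$class_code)
}

#' Build the friction surface
#'
#' Converts the merged class grid to per-cell orthogonal crossing times:
#' `minutes = (cell_size/1000) / speed_kmh * 60`. Barrier-mode cells are
#' masked impassable and carry no finite time. The surface is isotropic
#' (no slope correction); diagonal geometry is applied downstream by the
#' least-cost computation, so the stored surface is direction-free.
#'
#' @param merged A `merged_class_grid` from [merge_layers()].
#' @param scenario A `scenario_table` covering every class present (use
#'   [resolve_scenario()] first).
#' @return A `friction_grid` (a [geo_grid()] of minutes with a logical
#'   `barrier` mask).
#' @examples
#' lc <- geo_grid(matrix(10L, 2, 2), grid_spec(2, 2, cell_size = 100))
#' fr <- build_friction(merge_layers(lc), default_scenario())
#' fr$values[1, 1]  # 100 m at 5 km/h = 1.2 min
#' @export
build_friction <- function(merged, scenario) {
  spec <- merged$spec
  present <- unique(as.vector(merged$classes))
  unknown <- setdiff(present, scenario$class_code)
  if (length(unknown))
    stop("no scenario entry for class(es): ", paste(unknown, collapse = ", "),
         "; run resolve_scenario() first", call. = FALSE)
  i <- match(merged$classes, scenario$class_code)
  speed <- matrix(scenario$speed_kmh[i], spec$n_rows, spec$n_cols)
  barrier <- matrix(scenario$mode[i] == "barrier", spec$n_rows, spec$n_cols)
  minutes <- (spec$cell_size / 1000) / speed * 60
  minutes[barrier] <- NA_real_
  if (any(minutes[!barrier] <= 0, na.rm = TRUE))
    stop("non-positive crossing time computed; check scenario speeds",
         call. = FALSE)
  friction_grid(minutes, spec, barrier)
}

#' Construct a friction grid directly
#'
#' @param values Matrix of per-cell orthogonal crossing times (minutes);
#'   `NA` on barrier cells.
#' @param spec A [grid_spec()].
#' @param barrier Logical barrier mask (defaults to `is.na(values)`).
#' @return A `friction_grid`.
#' @export
friction_grid <- function(values, spec, barrier = is.na(values)) {
  g <- geo_grid(values, spec)
  stopifnot(is.logical(barrier), identical(dim(barrier), dim(values)))
  if (any(!is.na(values[barrier])))
    stop("barrier cells must not carry a finite crossing time", call. = FALSE)
  if (any(values[!barrier] <= 0 | is.na(values[!barrier])))
    stop("non-barrier cells need a finite positive crossing time", call. = FALSE)
  g$barrier <- barrier
  class(g) <- c("friction_grid", class(g))
  g
}
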