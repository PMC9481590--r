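#' Georeferenced lattice specification
#'
#' A `grid_spec` describes a regular, square-celled raster lattice in a
#' projected, metric coordinate reference system. The cell at (row 1,
#' col 1) sits at the north-west corner; rows increase southwards and
#' columns eastwards. Cell extents are half-open: a point on a cell's
#' western or northern edge belongs to that cell, so every point maps to
#' at most one cell.
#'
#' @param n_rows,n_cols Lattice dimensions (positive integers).
#' @param origin_x,origin_y Map coordinates (meters) of the north-west
#'   corner of the lattice (west edge / north edge).
#' @param cell_size Edge length of a (square) cell in meters.
#' @param crs_id Identifier of a projected, metric CRS. Geographic
#'   (longitude/latitude) identifiers are rejected: cell sizes and travel
#'   speeds are metric.
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(100, 100, 0, 10000, cell_size = 100)
#' cell_centroid(gs, 1, 1)  # (50, 9950)
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = n_rows * cell_size,
                      cell_size = 100, crs_id = "EPSG:3395") {
  stopifnot(is.numeric(n_rows), is.numeric(n_cols), length(n_rows) == 1L,
            length(n_cols) == 1L)
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number (meters)", call. = FALSE)
  if (is_geographic_crs(crs_id))
    stop("crs_id '", crs_id, "' looks geographic; a projected metric CRS is required",
         call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), crs_id = as.character(crs_id)),
    class = "grid_spec")
}

# crude but explicit: the ids users actually type for lon/lat systems
is_geographic_crs <- function(crs_id) {
  geo <- c("EPSG:4326", "EPSG:4269", "EPSG:4267", "WGS84", "WGS 84",
           "CRS84", "OGC:CRS84")
  toupper(crs_id) %in% toupper(geo) || grepl("longlat", crs_id, fixed = TRUE)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m, origin NW (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gm", x$n_rows, x$n_cols, x$cell_size)
}

grid_spec_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) <= tol && abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol && identical(a$crs_id, b$crs_id)
}

stop_if_grid_mismatch <- function(a, b, what = "grids") {
  if (!grid_spec_equal(a, b))
    stop("mismatched ", what, ": ", format(a), " (", a$crs_id, ") vs ",
         format(b), " (", b$crs_id, "); the pipeline refuses mixed grids",
         call. = FALSE)
  invisible(TRUE)
}

#' Map coordinates of cell centroids
#'
#' @param spec A [grid_spec()].
#' @param row,col Cell indices (1-based, vectorised).
#' @return A two-column matrix of (x, y) centroids.
#' @export
cell_centroid <- function(spec, row, col) {
  cbind(x = spec$origin_x + (col - 0.5) * spec$cell_size,
        y = spec$origin_y - (row - 0.5) * spec$cell_size)
}

#' Locate points on the lattice
#'
#' Maps map coordinates to (row, col) indices under the half-open cell
#' convention (west and north edges inclusive). Points outside the
#' lattice get `NA` indices.
#'
#' @param spec A [grid_spec()].
#' @param x,y Coordinate vectors.
#' @return A data frame with integer columns `row`, `col`.
#' @export
point_to_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  # north/west edge inclusive: y == origin_y gives row 1 already; the
  # south/east outer edges fall outside
  bad <- row < 1 | row > spec$n_rows | col < 1 | col > spec$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster grid
#'
#' A `geo_grid` couples a value matrix with its [grid_spec()]. `NA`
#' entries are nodata. This is the in-memory form of every raster in the
#' pipeline (landcover classes, friction, travel time, population).
#'
#' @param values Numeric matrix with `spec$n_rows` rows.
#' @param spec A [grid_spec()].
#' @param name Optional dataset name (used for population grids).
#' @return An object of class `geo_grid`.
#' @export
geo_grid <- function(values, spec, name = NULL) {
  stopifnot(is.matrix(values))
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("value matrix is ", nrow(values), "x", ncol(values),
         " but spec says ", spec$n_rows, "x", spec$n_cols, call. = FALSE)
  structure(list(values = values, spec = spec, name = name), class = "geo_grid")
}

#' @export
print.geo_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<%s> %s CRS %s%s\n", class(x)[1], format(x$spec), x$spec$crs_id,
              if (!is.null(x$name)) paste0(" dataset '", x$name, "'") else ""))
  if (length(v))
    cat(sprintf("  finite cells: %d  range [%g, %g]  sum %g\n",
                length(v), min(v), max(v), sum(v)))
  invisible(x)
}

#' Tidy view of a raster grid
#'
#' One row per cell with centroid coordinates; useful for ggplot2 and for
#' joining rasters with point tables.
#'
#' @param x A `geo_grid`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.geo_grid <- function(x, ...) {
  sp <- x$spec
  idx <- expand.grid(row = seq_len(sp$n_rows), col = seq_len(sp$n_cols))
  ctr <- cell_centroid(sp, idx$row, idx$col)
  tibble::tibble(row = idx$row, col = idx$col,
                 x = ctr[, 1], y = ctr[, 2],
                 value = as.vector(x$values))
}

#' @export
autoplot.geo_grid <- function(object, ...) {
  df <- as_tibble.geo_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  fill = object$name %||% "value") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
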