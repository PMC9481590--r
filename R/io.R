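#' Write a raster grid to an Esri ASCII grid file
#'
#' Rasters are serialized as plain-text Esri ASCII grids (`.asc`), a
#' single-band georeferenced format readable by every GIS. `NA` cells are
#' written as the nodata value. The CRS identifier — which the `.asc`
#' header cannot carry — goes to a `.prj` sidecar next to the file.
#'
#' @param grid A [geo_grid()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Numeric nodata marker written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "geo_grid"))
  sp <- grid$spec
  vals <- grid$values
  if (any(is.finite(vals) & vals == nodata, na.rm = TRUE))
    stop("nodata value ", nodata, " collides with a data value", call. = FALSE)
  hdr <- c(
    sprintf("ncols %d", sp$n_cols),
    sprintf("nrows %d", sp$n_rows),
    sprintf("xllcorner %.10g", sp$origin_x),
    sprintf("yllcorner %.10g", sp$origin_y - sp$n_rows * sp$cell_size),
    sprintf("cellsize %.10g", sp$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  m <- vals
  m[is.na(m)] <- nodata
  rows <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(sp$crs_id, prj_path(path))
  invisible(path)
}

prj_path <- function(path) paste0(sub("\\.asc$", "", path), ".prj")

#' Read a raster grid from an Esri ASCII grid file
#'
#' The inverse of [write_raster()]: values are taken as stored (no
#' resampling), nodata cells become `NA`, and the CRS id is read from the
#' `.prj` sidecar when present.
#'
#' @param path Path to a single-band `.asc` raster.
#' @param crs_id Override for the CRS id if there is no sidecar.
#' @return A [geo_grid()].
#' @export
read_raster <- function(path, crs_id = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a single-band Esri ASCII grid (missing header keys): ", path,
         call. = FALSE)
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop("raster body has ", length(body), " rows, header says ", hdr$nrows,
         call. = FALSE)
  vals <- do.call(rbind, lapply(body, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
  if (ncol(vals) != hdr$ncols)
    stop("raster body has ", ncol(vals), " cols, header says ", hdr$ncols,
         call. = FALSE)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  if (is.null(crs_id)) {
    pp <- prj_path(path)
    if (!file.exists(pp))
      stop("unreadable CRS: no .prj sidecar for ", path,
           " and no crs_id supplied", call. = FALSE)
    crs_id <- trimws(readLines(pp, n = 1))
  }
  spec <- grid_spec(hdr$nrows, hdr$ncols,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    cell_size = hdr$cellsize, crs_id = crs_id)
  geo_grid(vals, spec)
}

# ---- vector features ---------------------------------------------------

#' Construct a feature collection
#'
#' Features are a tibble with a `geometry` list-column (each element a
#' two-column coordinate matrix; a single row for points, a vertex path
#' for lines, a closed outer ring for polygons) plus arbitrary attribute
#' columns. The geometry kind and CRS id travel as attributes.
#'
#' @param geometry List of two-column coordinate matrices.
#' @param kind One of `"point"`, `"line"`, `"polygon"`.
#' @param crs_id CRS identifier string.
#' @param ... Attribute vectors, one value per feature.
#' @return A tibble of class `geo_features`.
#' @export
geo_features <- function(geometry, kind, crs_id = "EPSG:3395", ...) {
  kind <- match.arg(kind, c("point", "line", "polygon"))
  attrs <- tibble::tibble(...)
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    colnames(g) <- c("x", "y")
    g
  })
  out <- tibble::tibble(geometry = geometry)
  if (ncol(attrs)) out <- dplyr::bind_cols(out, attrs)
  structure(out, class = c("geo_features", class(out)),
            kind = kind, crs_id = crs_id)
}

feature_kind <- function(x) attr(x, "kind", exact = TRUE)
feature_crs <- function(x) attr(x, "crs_id", exact = TRUE)

geojson_type <- c(point = "Point", line = "LineString", polygon = "Polygon")

#' Write features to GeoJSON
#'
#' The CRS id is stored as a top-level `crs_id` foreign member (GeoJSON
#' proper is CRS-less); coordinates are written as-is in map units.
#'
#' @param features A [geo_features()] collection.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(features, path) {
  kind <- feature_kind(features)
  props <- features[setdiff(names(features), "geometry")]
  feats <- lapply(seq_len(nrow(features)), function(j) {
    g <- features$geometry[[j]]
    coords <- switch(kind,
      point = as.numeric(g[1, ]),
      line = unname(lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ]))),
      polygon = list(unname(lapply(seq_len(nrow(g)), function(r) as.numeric(g[r, ])))))
    pr <- if (ncol(props)) as.list(props[j, , drop = FALSE]) else
      stats::setNames(list(), character())
    list(type = "Feature",
         geometry = list(type = unname(geojson_type[kind]), coordinates = coords),
         properties = pr)
  })
  obj <- list(type = "FeatureCollection", crs_id = feature_crs(features),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read features from GeoJSON
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @param geometry_kind Expected kind: `"point"`, `"line"` or `"polygon"`;
#'   a file holding a different kind is an error, never a coercion.
#' @return A [geo_features()] collection; empty files yield an empty
#'   collection with a warning.
#' @export
read_vectors <- function(path, geometry_kind) {
  geometry_kind <- match.arg(geometry_kind, c("point", "line", "polygon"))
  if (!file.exists(path)) stop("vector file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crs_id <- obj$crs_id %||% "EPSG:3395"
  feats <- obj$features %||% list()
  if (!length(feats)) {
    warning("empty feature collection: ", path, call. = FALSE)
    return(geo_features(list(), geometry_kind, crs_id))
  }
  want <- geojson_type[geometry_kind]
  geoms <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (j in seq_along(feats)) {
    f <- feats[[j]]
    ty <- f$geometry$type
    if (!identical(ty, unname(want)))
      stop("geometry kind mismatch in ", path, ": wanted ", want,
           ", found ", ty, call. = FALSE)
    co <- f$geometry$coordinates
    geoms[[j]] <- switch(geometry_kind,
      point = matrix(unlist(co), ncol = 2),
      line = do.call(rbind, lapply(co, unlist)),
      polygon = do.call(rbind, lapply(co[[1]], unlist)))
    props[[j]] <- lapply(f$properties %||% list(), function(v) v %||% NA)
  }
  attr_tbl <- if (length(props[[1]]))
    dplyr::bind_rows(lapply(props, tibble::as_tibble)) else NULL
  out <- geo_features(geoms, geometry_kind, crs_id)
  if (!is.null(attr_tbl)) {
    out2 <- dplyr::bind_cols(tibble::tibble(geometry = out$geometry), attr_tbl)
    out <- structure(out2, class = c("geo_features", class(out2)),
                     kind = geometry_kind, crs_id = crs_id)
  }
  out
}

# ---- travel scenario ---------------------------------------------------

#' Read and validate a travel-scenario table
#'
#' A travel scenario maps merged-grid class codes to travel speeds: road
#' classes to motorized speeds, landcover classes to walking speeds, and
#' water classes to impassable barriers. Accepted as CSV (columns
#' `class_code,label,mode,speed_kmh`) or YAML (list of row maps).
#'
#' @param path Path to a `.csv` or `.yml`/`.yaml` scenario file.
#' @return A validated `scenario_table` tibble.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    rows <- yaml::read_yaml(path)
    df <- dplyr::bind_rows(lapply(rows, function(r) {
      tibble::tibble(class_code = r$class_code, label = r$label, mode = r$mode,
                     speed_kmh = if (is.null(r$speed_kmh)) NA_real_ else r$speed_kmh)
    }))
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(
      class_code = readr::col_integer(), label = readr::col_character(),
      mode = readr::col_character(), speed_kmh = readr::col_double()))
  }
  as_scenario_table(df)
}

#' Validate a scenario data frame
#'
#' @param df Data frame with columns `class_code`, `label`, `mode`,
#'   `speed_kmh` (`NA` allowed only for barrier rows).
#' @return The validated tibble, classed `scenario_table`.
#' @export
as_scenario_table <- function(df) {
  need <- c("class_code", "label", "mode", "speed_kmh")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scenario table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- tibble::as_tibble(df)[need]
  df$class_code <- as.integer(df$class_code)
  if (anyDuplicated(df$class_code))
    stop("duplicate class_code in scenario: ",
         paste(unique(df$class_code[duplicated(df$class_code)]), collapse = ", "),
         call. = FALSE)
  bad_mode <- setdiff(unique(df$mode), c("road", "offroad", "barrier"))
  if (length(bad_mode))
    stop("unknown scenario mode(s): ", paste(bad_mode, collapse = ", "),
         call. = FALSE)
  nb <- df$mode != "barrier"
  if (any(is.na(df$speed_kmh[nb]) | df$speed_kmh[nb] <= 0))
    stop("non-barrier scenario rows need speed_kmh > 0; offending class_code: ",
         paste(df$class_code[nb & (is.na(df$speed_kmh) | df$speed_kmh <= 0)],
               collapse = ", "), call. = FALSE)
  if (any(is.finite(df$speed_kmh[!nb])))
    stop("barrier rows must not carry a finite speed; offending class_code: ",
         paste(df$class_code[!nb & is.finite(df$speed_kmh)], collapse = ", "),
         call. = FALSE)
  structure(df, class = c("scenario_table", class(df)))
}

#' Write a scenario table as CSV
#'
#' @param scenario A `scenario_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  readr::write_csv(scenario, path, na = "")
  invisible(path)
}

#' Built-in travel scenario for synthetic worlds
#'
#' Speeds follow the usual accessibility-modelling convention: motorized
#' travel on roads, walking off-road, waterbodies impassable. Road
#' speeds are continental-average class speeds; off-road walking is
#' 5 km/h in open terrain and 2 km/h under dense canopy.
#'
#' @return A `scenario_table`.
#' @export
default_scenario <- function() {
  as_scenario_table(tibble::tribble(
    ~class_code, ~label,           ~mode,     ~speed_kmh,
    1L,  "primary road",    "road",    80,
    2L,  "secondary road",  "road",    50,
    3L,  "tertiary road",   "road",    30,
    10L, "open terrain",    "offroad", 5,
    20L, "dense forest",    "offroad", 2,
    30L, "settlement",      "offroad", 5,
    200L, "waterbody",      "barrier", NA_real_))
}

#' Continental-average fallback speeds per road class
#'
#' Used by [resolve_scenario()] to fill classes a scenario omits, the way
#' a per-country scenario falls back to a continental average speed for a
#' road class it does not list.
#'
#' @return A tibble with `class_code`, `label`, `mode`, `speed_kmh`.
#' @export
default_fallback <- function() {
  tibble::tribble(
    ~class_code, ~label,          ~mode,  ~speed_kmh,
    1L, "primary road",   "road", 80,
    2L, "secondary road", "road", 50,
    3L, "tertiary road",  "road", 30,
    4L, "trunk road",     "road", 70)
}
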