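#' Configuration for a synthetic world
#'
#' The generator emulates the input stack of a continental accessibility
#' analysis at desk scale: clustered settlements of households on a
#' landcover lattice, a spanning road network, river barriers, nested
#' administrative units of uneven size, and facilities at a subset of
#' settlements. Defaults describe a sparsely settled 16 x 16 km rural
#' region at 100-m resolution — the regime where gridded population
#' products disagree most; see the methods vignette for the reasoning
#' behind each value.
#'
#' @param n_rows,n_cols Lattice size in cells.
#' @param cell_size Cell edge in meters.
#' @param crs_id Projected CRS identifier for all layers.
#' @param n_settlements Number of settlement clusters (>= 1).
#' @param population_total Total population; conserved exactly.
#' @param household_size Persons per household point.
#' @param settlement_spread_cells Gaussian dispersion of households
#'   around their settlement center, in cells (the parent-child process
#'   scale; larger = more diffuse settlements).
#' @param settlement_min_sep_cells Minimum separation between settlement
#'   centers, in cells (controls sparsity).
#' @param n_facilities Facilities, placed at distinct settlement centers.
#' @param n_rivers Number of meandering river barriers.
#' @param n_forest_patches,forest_patch_radius_cells Low-speed landcover
#'   patches.
#' @param admin1_nx,admin1_ny Level-1 guillotine partition (columns x
#'   rows of unequal rectangles).
#' @param admin2_nx,admin2_ny Level-2 subdivision of each level-1 unit.
#' @return A `world_config` list.
#' @export
world_config <- function(n_rows = 160, n_cols = 160, cell_size = 100,
                         crs_id = "EPSG:3395",
                         n_settlements = 12, population_total = 20000,
                         household_size = 5,
                         settlement_spread_cells = 2.5,
                         settlement_min_sep_cells = 15,
                         n_facilities = 3, n_rivers = 1,
                         n_forest_patches = 5, forest_patch_radius_cells = 18,
                         admin1_nx = 2, admin1_ny = 2,
                         admin2_nx = 2, admin2_ny = 2) {
  cfg <- as.list(environment())
  structure(cfg, class = "world_config")
}

# one substream per generation stage, so stages are independently
# reproducible and adding a stage never perturbs earlier ones
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 1009 + k * 9973) %% 2147483629)
}

# landcover codes used by the generator (match default_scenario())
LC_OPEN <- 10L
LC_FOREST <- 20L
LC_SETTLEMENT <- 30L
LC_WATER <- 200L

#' Generate a synthetic world
#'
#' Builds a fully self-contained study region with ground truth: the
#' household points are the true population, against which every
#' allocation scheme and coverage statistic can be referenced. All
#' randomness flows from `seed` through one substream per stage.
#'
#' @param config A [world_config()].
#' @param seed Integer seed fixing all randomness.
#' @return A `synthetic_world` object: `spec`, `landcover` ([geo_grid()]
#'   of class codes), `water_mask`, `settlements`, `households`, `roads`,
#'   `rivers`, `facilities`, `admin_units`, `config`, `seed`.
#' @export
make_world <- function(config = world_config(), seed = 1) {
  cfg <- config
  if (cfg$n_settlements < 1)
    stop("n_settlements must be >= 1 (no facilities placeable otherwise)",
         call. = FALSE)
  if (cfg$n_facilities < 1 || cfg$n_facilities > cfg$n_settlements)
    stop("n_facilities must be between 1 and n_settlements", call. = FALSE)
  spec <- grid_spec(cfg$n_rows, cfg$n_cols, origin_x = 0,
                    origin_y = cfg$n_rows * cfg$cell_size,
                    cell_size = cfg$cell_size, crs_id = cfg$crs_id)
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size
  landcover <- matrix(LC_OPEN, nr, nc)

  # -- forest patches ----------------------------------------------------
  set.seed(stage_seed(seed, 1))
  if (cfg$n_forest_patches > 0) {
    for (p in seq_len(cfg$n_forest_patches)) {
      cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
      rad <- cfg$forest_patch_radius_cells * stats::runif(1, 0.6, 1.2)
      rows <- pmax(1, floor(cr - rad)):pmin(nr, ceiling(cr + rad))
      cols <- pmax(1, floor(cc - rad)):pmin(nc, ceiling(cc + rad))
      sub <- expand.grid(row = rows, col = cols)
      hit <- (sub$row - cr)^2 + (sub$col - cc)^2 <= rad^2
      landcover[cbind(sub$row[hit], sub$col[hit])] <- LC_FOREST
    }
  }

  # -- rivers ------------------------------------------------------------
  set.seed(stage_seed(seed, 2))
  river_geoms <- list()
  if (cfg$n_rivers > 0) {
    for (rv in seq_len(cfg$n_rivers)) {
      x <- stats::runif(1, 0.25, 0.75) * nc * cs
      ys <- seq(spec$origin_y, spec$origin_y - nr * cs, by = -4 * cs)
      xs <- x + cumsum(c(0, stats::rnorm(length(ys) - 1, 0, 1.5 * cs)))
      xs <- pmin(pmax(xs, 0.05 * nc * cs), 0.95 * nc * cs)
      river_geoms[[rv]] <- cbind(x = xs, y = ys)
    }
  }
  rivers <- geo_features(river_geoms, "line", crs_id = cfg$crs_id)
  water_mask <- rasterize_barriers(rivers, NULL, spec)
  landcover[water_mask] <- LC_WATER

  # -- admin partition (guillotine, cell-aligned, unequal sizes) ---------
  set.seed(stage_seed(seed, 3))
  admin_units <- make_admin_partition(spec, cfg)

  # -- settlements and households ---------------------------------------
  set.seed(stage_seed(seed, 4))
  margin <- 3
  open_cells <- which(!water_mask, arr.ind = TRUE)
  open_cells <- open_cells[open_cells[, 1] > margin & open_cells[, 1] <= nr - margin &
                             open_cells[, 2] > margin & open_cells[, 2] <= nc - margin, ,
                           drop = FALSE]
  centers <- matrix(numeric(), 0, 2)
  tries <- 0L
  while (nrow(centers) < cfg$n_settlements) {
    tries <- tries + 1L
    if (tries > 1000L * cfg$n_settlements || !nrow(open_cells))
      stop("domain too small to place ", cfg$n_settlements,
           " settlements at min separation ", cfg$settlement_min_sep_cells,
           " cells", call. = FALSE)
    cand <- open_cells[sample.int(nrow(open_cells), 1L), ]
    if (nrow(centers) == 0 ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >=
        cfg$settlement_min_sep_cells^2)
      centers <- rbind(centers, cand)
  }
  ctr_xy <- cell_centroid(spec, centers[, 1], centers[, 2])

  n_households <- max(cfg$n_settlements, round(cfg$population_total / cfg$household_size))
  w <- stats::rlnorm(cfg$n_settlements, 0, 0.8)
  counts <- floor(w / sum(w) * n_households)
  counts <- counts + largest_remainder(w / sum(w) * n_households - counts,
                                       n_households - sum(counts))
  if (any(counts == 0)) {  # every settlement has at least one household
    need <- counts == 0
    counts[need] <- 1L
    counts[which.max(counts)] <- counts[which.max(counts)] - sum(need)
  }
  hh <- vector("list", cfg$n_settlements)
  for (i in seq_len(cfg$n_settlements)) {
    k <- counts[i]
    pos <- matrix(NA_real_, k, 2)
    for (h in seq_len(k)) {
      for (try in 1:50) {
        x <- ctr_xy[i, 1] + stats::rnorm(1, 0, cfg$settlement_spread_cells * cs)
        y <- ctr_xy[i, 2] + stats::rnorm(1, 0, cfg$settlement_spread_cells * cs)
        cl <- point_to_cell(spec, x, y)
        if (!is.na(cl$row) && !water_mask[cl$row, cl$col]) break
        x <- ctr_xy[i, 1]; y <- ctr_xy[i, 2]
      }
      pos[h, ] <- c(x, y)
    }
    hh[[i]] <- tibble::tibble(x = pos[, 1], y = pos[, 2], settlement_id = i)
  }
  households <- dplyr::bind_rows(hh)
  households$weight <- cfg$population_total / n_households

  hh_cells <- point_to_cell(spec, households$x, households$y)
  landcover[unique(cbind(hh_cells$row, hh_cells$col))] <- LC_SETTLEMENT
  footprints <- lapply(seq_len(cfg$n_settlements), function(i) {
    sel <- households$settlement_id == i
    unique(cbind(row = hh_cells$row[sel], col = hh_cells$col[sel]))
  })
  settlements <- tibble::tibble(
    id = seq_len(cfg$n_settlements),
    x = ctr_xy[, 1], y = ctr_xy[, 2],
    row = as.integer(centers[, 1]), col = as.integer(centers[, 2]),
    n_households = as.integer(counts), footprint = footprints)

  # -- roads: MST over settlement centers (contains every settlement's
  #    nearest-neighbour edge, hence spanning connectivity) --------------
  set.seed(stage_seed(seed, 5))
  roads <- make_roads(settlements, cfg$crs_id)

  # -- facilities at a subset of settlement centers ----------------------
  set.seed(stage_seed(seed, 6))
  fac_idx <- sort(sample.int(cfg$n_settlements, cfg$n_facilities))
  facilities <- tibble::tibble(settlement_id = fac_idx,
                               x = settlements$x[fac_idx],
                               y = settlements$y[fac_idx])

  structure(list(spec = spec,
                 landcover = geo_grid(landcover, spec, name = "landcover"),
                 water_mask = water_mask,
                 settlements = settlements, households = households,
                 roads = roads, rivers = rivers, facilities = facilities,
                 admin_units = admin_units, config = cfg, seed = seed),
            class = "synthetic_world")
}

largest_remainder <- function(frac, k) {
  add <- integer(length(frac))
  if (k > 0) add[order(frac, decreasing = TRUE)[seq_len(k)]] <- 1L
  add
}

make_admin_partition <- function(spec, cfg) {
  nr <- spec$n_rows; nc <- spec$n_cols; cs <- spec$cell_size
  rand_breaks <- function(n_cells, k) {
    # k segments of random, unequal, cell-aligned widths (>= 10% each)
    p <- stats::runif(k, 0.4, 1.6)
    b <- round(cumsum(p / sum(p)) * n_cells)
    b <- pmax(b, seq_len(k))        # at least one cell per segment
    b[k] <- n_cells
    unique(c(0, b))
  }
  xb1 <- rand_breaks(nc, cfg$admin1_nx)
  yb1 <- rand_breaks(nr, cfg$admin1_ny)
  rect_ring <- function(c0, c1, r0, r1) {
    x0 <- spec$origin_x + c0 * cs; x1 <- spec$origin_x + c1 * cs
    y0 <- spec$origin_y - r0 * cs; y1 <- spec$origin_y - r1 * cs
    cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
  }
  rows <- list()
  u1 <- 0L
  for (ix in seq_len(length(xb1) - 1)) for (iy in seq_len(length(yb1) - 1)) {
    u1 <- u1 + 1L
    id1 <- sprintf("A%d", u1)
    c0 <- xb1[ix]; c1 <- xb1[ix + 1]; r0 <- yb1[iy]; r1 <- yb1[iy + 1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = id1, level = 1L, parent_id = NA_character_,
      geometry = list(rect_ring(c0, c1, r0, r1)),
      area_km2 = (c1 - c0) * (r1 - r0) * cs^2 / 1e6)
    xb2 <- c0 + rand_breaks(c1 - c0, cfg$admin2_nx)
    yb2 <- r0 + rand_breaks(r1 - r0, cfg$admin2_ny)
    u2 <- 0L
    for (jx in seq_len(length(xb2) - 1)) for (jy in seq_len(length(yb2) - 1)) {
      u2 <- u2 + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("%s-%d", id1, u2), level = 2L, parent_id = id1,
        geometry = list(rect_ring(xb2[jx], xb2[jx + 1], yb2[jy], yb2[jy + 1])),
        area_km2 = (xb2[jx + 1] - xb2[jx]) * (yb2[jy + 1] - yb2[jy]) * cs^2 / 1e6)
    }
  }
  dplyr::bind_rows(rows)
}

make_roads <- function(settlements, crs_id) {
  n <- nrow(settlements)
  if (n < 2)
    return(geo_features(list(), "line", crs_id = crs_id, class_code = integer()))
  d <- as.matrix(stats::dist(cbind(settlements$x, settlements$y)))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst, names = FALSE)
  len <- d[el]
  # longer trunk links get faster classes, short spurs are tertiary
  cls <- as.integer(cut(rank(-len, ties.method = "first"), 3, labels = FALSE))
  geoms <- lapply(seq_len(nrow(el)), function(e)
    cbind(x = settlements$x[el[e, ]], y = settlements$y[el[e, ]]))
  geo_features(geoms, "line", crs_id = crs_id, class_code = cls)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %s, %d settlements, %d households (%g people),\n",
              format(x$spec), nrow(x$settlements), nrow(x$households),
              sum(x$households$weight)))
  cat(sprintf("  %d facilities, %d roads, %d rivers, %d admin units (L1 %d / L2 %d)\n",
              nrow(x$facilities), nrow(x$roads), nrow(x$rivers),
              nrow(x$admin_units), sum(x$admin_units$level == 1),
              sum(x$admin_units$level == 2)))
  invisible(x)
}

#' Population allocation scheme
#'
#' The three redistribution families real gridded products fall into:
#' `constrained` places a census unit's total only on detected
#' settlement footprints (with a configurable footprint miss rate
#' emulating imperfect building detection); `unconstrained_uniform`
#' spreads it equally over every non-water cell of the unit;
#' `unconstrained_covariate` weights cells by a Gaussian-smoothed
#' settlement-proximity covariate perturbed by lognormal noise, an
#' intermediate, dasymetric-like behaviour.
#'
#' @param name Dataset name for the resulting raster.
#' @param kind One of `"constrained"`, `"unconstrained_uniform"`,
#'   `"unconstrained_covariate"`.
#' @param census_unit_level Level the scheme redistributes within: 1
#'   (coarse), 2 (fine) or `"domain"`.
#' @param miss_rate Probability a settlement's footprint goes undetected
#'   (constrained kind); in `[0, 1)`.
#' @param noise_scale Lognormal sd of the covariate perturbation (>= 0).
#' @param smooth_sigma Gaussian smoothing sd of the settlement
#'   indicator, in cells.
#' @return An `allocation_scheme` list.
#' @export
allocation_scheme <- function(name, kind = c("constrained", "unconstrained_uniform",
                                             "unconstrained_covariate"),
                              census_unit_level = 2, miss_rate = 0.1,
                              noise_scale = 0.5, smooth_sigma = 4) {
  kind <- match.arg(kind)
  if (miss_rate < 0 || miss_rate >= 1)
    stop("miss_rate must be in [0, 1)", call. = FALSE)
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (!(identical(census_unit_level, "domain") || census_unit_level %in% c(1, 2)))
    stop("census_unit_level must be 1, 2 or 'domain'", call. = FALSE)
  structure(list(name = name, kind = kind,
                 census_unit_level = census_unit_level,
                 miss_rate = miss_rate, noise_scale = noise_scale,
                 smooth_sigma = smooth_sigma),
            class = "allocation_scheme")
}

# separable gaussian blur with zero padding; sigma in cells
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(m) {  # along rows (vertical)
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) {
      src <- seq_len(nrow(m)) + o
      ok <- src >= 1 & src <= nrow(m)
      out[ok, ] <- out[ok, ] + k[o + r + 1] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(smooth1(t(smooth1(mat))))
}

#' Allocate the true population onto a raster under a scheme
#'
#' Redistributes each census unit's true household total within that
#' unit according to the scheme — never across units, so per-unit totals
#' are preserved exactly and the domain total is conserved by
#' construction. A constrained unit whose footprints were all missed
#' falls back to uniform spreading with a warning, mirroring real
#' products' fallback behaviour.
#'
#' @param world A `synthetic_world`.
#' @param scheme An [allocation_scheme()].
#' @param seed Seed for the scheme's randomness (footprint misses,
#'   covariate noise); defaults to a substream of the world seed keyed by
#'   the scheme name.
#' @param coarsen Integer block factor (>= 1) aggregating the result to a
#'   coarser lattice, emulating products released at coarser resolution;
#'   must divide the lattice dimensions.
#' @return A `population_grid` named after the scheme.
#' @export
allocate_population <- function(world, scheme, seed = NULL, coarsen = 1L) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(scheme, "allocation_scheme"))
  spec <- world$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  if (is.null(seed))
    seed <- stage_seed(world$seed, 100L + sum(utf8ToInt(scheme$name)))
  set.seed(seed)

  unit_of_cell <- cell_units(world, scheme$census_unit_level)
  hh <- world$households
  hc <- point_to_cell(spec, hh$x, hh$y)
  hh_cell <- (hc$col - 1L) * nr + hc$row
  hh_unit <- unit_of_cell[hh_cell]
  truth <- tapply(hh$weight, hh_unit, sum)

  land <- !world$water_mask
  w <- matrix(0, nr, nc)
  if (scheme$kind == "constrained") {
    detected <- stats::runif(nrow(world$settlements)) >= scheme$miss_rate
    sel <- hh$settlement_id %in% world$settlements$id[detected]
    if (any(sel)) {
      tab <- tapply(hh$weight[sel], hh_cell[sel], sum)
      w[as.integer(names(tab))] <- as.numeric(tab)
    }
  } else if (scheme$kind == "unconstrained_uniform") {
    w[land] <- 1
  } else {
    ind <- matrix(0, nr, nc)
    ind[world$landcover$values == LC_SETTLEMENT] <- 1
    sm <- gauss_smooth(ind, scheme$smooth_sigma)
    noise <- if (scheme$noise_scale > 0)
      matrix(exp(stats::rnorm(nr * nc, 0, scheme$noise_scale)), nr, nc) else 1
    w <- (sm + 1e-8 * max(sm)) * noise
    w[!land] <- 0
  }

  vals <- matrix(0, nr, nc)
  for (u in names(truth)) {
    in_unit <- unit_of_cell == u
    s <- sum(w[in_unit])
    if (s > 0) {
      vals[in_unit] <- truth[[u]] * w[in_unit] / s
    } else {
      fb <- in_unit & land
      if (!any(fb)) fb <- in_unit
      vals[fb] <- truth[[u]] / sum(fb)
      warning("unit ", u, ": no allocation support under scheme '",
              scheme$name, "'; fell back to uniform spreading", call. = FALSE)
    }
  }

  out_spec <- spec
  if (coarsen > 1L) {
    if (nr %% coarsen || nc %% coarsen)
      stop("coarsen factor must divide the lattice dimensions", call. = FALSE)
    vals <- block_sum(vals, coarsen)
    out_spec <- grid_spec(nr / coarsen, nc / coarsen, spec$origin_x,
                          spec$origin_y, spec$cell_size * coarsen, spec$crs_id)
  }
  structure(population_grid(vals, out_spec, name = scheme$name),
            scheme = scheme)
}

cell_units <- function(world, level) {
  spec <- world$spec
  if (identical(level, "domain"))
    return(matrix("domain", spec$n_rows, spec$n_cols))
  idx <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  ctr <- cell_centroid(spec, idx$row, idx$col)
  matrix(assign_units(ctr[, 1], ctr[, 2], world$admin_units, level),
         spec$n_rows, spec$n_cols)
}

block_sum <- function(m, f) {
  nr <- nrow(m) / f; nc <- ncol(m) / f
  # sum f x f blocks: fold rows, then columns
  m1 <- rowsum(m, rep(seq_len(nr), each = f))
  t(rowsum(t(m1), rep(seq_len(nc), each = f)))
}

#' Ground-truth accessibility coverage of the household population
#'
#' The fraction of true household weight whose containing cell has
#' travel time at or below the threshold. Households on barrier cells
#' are excluded from numerator and denominator and tallied; unreachable
#' households stay in the denominator.
#'
#' @param world A `synthetic_world`.
#' @param tt A `travel_time_grid` computed on the world's friction
#'   surface (same lattice).
#' @param threshold Travel-time threshold in minutes.
#' @return Fraction in `[0, 1]`, with attributes `pop_on_barrier` and
#'   `pop_total` (non-barrier weight).
#' @export
true_coverage <- function(world, tt, threshold) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(tt, "travel_time_grid"))
  stop_if_grid_mismatch(world$spec, tt$spec)
  hh <- world$households
  hc <- point_to_cell(world$spec, hh$x, hh$y)
  v <- tt$values[cbind(hc$row, hc$col)]
  on_barrier <- is.na(v)
  denom <- sum(hh$weight[!on_barrier])
  num <- sum(hh$weight[!on_barrier & is.finite(v) & v <= threshold])
  frac <- if (denom > 0) num / denom else 0
  structure(frac, pop_on_barrier = sum(hh$weight[on_barrier]),
            pop_total = denom)
}

#' Build the world's friction surface
#'
#' Convenience wrapper chaining the friction module over a synthetic
#' world: rasterizes roads, merges with the landcover lattice and river
#' barriers under bridge priority, resolves the scenario and builds the
#' crossing-time surface.
#'
#' @param world A `synthetic_world`.
#' @param scenario A `scenario_table`; defaults to [default_scenario()].
#' @return A `friction_grid`.
#' @export
world_friction <- function(world, scenario = default_scenario()) {
  spec <- world$spec
  road_classes <- rasterize_lines(world$roads, spec, scenario)
  # landcover already carries the water class; the explicit mask keeps
  # river cells barriers even where forest/settlement painting followed
  merged <- merge_layers(world$landcover, road_classes, world$water_mask)
  scenario <- resolve_scenario(scenario, unique(as.vector(merged$classes)))
  build_friction(merged, scenario)
}

#' Export a synthetic world to files
#'
#' Writes the landcover raster (`.asc`), vector layers (GeoJSON),
#' households and a manifest YAML recording the seed and generating
#' config.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  crs <- world$spec$crs_id
  write_raster(world$landcover, file.path(dir, "landcover.asc"))
  write_vectors(world$roads, file.path(dir, "roads.geojson"))
  write_vectors(world$rivers, file.path(dir, "rivers.geojson"))
  pts <- function(df, ...) geo_features(
    lapply(seq_len(nrow(df)), function(i) cbind(df$x[i], df$y[i])),
    "point", crs_id = crs, ...)
  write_vectors(pts(world$facilities, settlement_id = world$facilities$settlement_id),
                file.path(dir, "facilities.geojson"))
  write_vectors(pts(world$households, weight = world$households$weight,
                    settlement_id = world$households$settlement_id),
                file.path(dir, "households.geojson"))
  for (lv in 1:2) {
    au <- world$admin_units[world$admin_units$level == lv, ]
    write_vectors(geo_features(au$geometry, "polygon", crs_id = crs,
                               id = au$id, parent_id = au$parent_id,
                               area_km2 = au$area_km2),
                  file.path(dir, sprintf("admin%d.geojson", lv)))
  }
  manifest <- list(seed = world$seed, config = unclass(world$config),
                   files = c("landcover.asc", "roads.geojson", "rivers.geojson",
                             "facilities.geojson", "households.geojson",
                             "admin1.geojson", "admin2.geojson"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
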