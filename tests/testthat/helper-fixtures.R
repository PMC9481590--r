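# Small world for functional tests (not the study conditions used by
# the acceptance suite, which run at the generator defaults).
small_config <- function(...) {
  defaults <- list(n_rows = 60, n_cols = 60, cell_size = 100,
                   n_settlements = 6, population_total = 6000,
                   household_size = 5, settlement_min_sep_cells = 8,
                   n_facilities = 2, n_rivers = 1, n_forest_patches = 2,
                   forest_patch_radius_cells = 8)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

small_world_tt <- function(seed = 42, config = small_config()) {
  w <- make_world(config, seed = seed)
  fr <- world_friction(w)
  seeds <- suppressMessages(seed_facilities(w$facilities, fr))
  tt <- least_cost_travel_time(fr, seeds)
  list(world = w, friction = fr, tt = tt)
}

# Classified-point tibble built directly, for coverage/compare tests.
demo_points <- function(count, travel_time_min, status = "finite",
                        dataset = "demo", admin1_id = NA_character_,
                        admin2_id = NA_character_) {
  st <- rep_len(status, length(count))
  tt <- rep_len(travel_time_min, length(count))
  tt[st != "finite"] <- NA_real_
  tibble::tibble(x = seq_along(count), y = 1, count = count,
                 dataset = dataset, admin1_id = admin1_id,
                 admin2_id = admin2_id, travel_time_min = tt, status = st)
}

uniform_friction <- function(n, t = 1, cell = 100) {
  friction_grid(matrix(t, n, n), grid_spec(n, n, cell_size = cell))
}

seeds_at <- function(fr, rows, cols) {
  ctr <- cell_centroid(fr$spec, rows, cols)
  seed_facilities(data.frame(x = ctr[, 1], y = ctr[, 2]), fr)
}

# per-admin-unit household totals: the ground truth allocation schemes
# must preserve
unit_truth <- function(world, level) {
  hh <- world$households
  zero_tt <- travel_time_grid(matrix(0, world$spec$n_rows,
                                     world$spec$n_cols), world$spec)
  pts <- structure(tibble::tibble(x = hh$x, y = hh$y, count = hh$weight,
                                  dataset = "truth"),
                   crs_id = world$spec$crs_id)
  ids <- classify_points(pts, zero_tt, world$admin_units,
                         levels = level)[[paste0("admin", level, "_id")]]
  tapply(hh$weight, ids, sum)
}

# cell -> admin unit id matrix (centroid rule)
cell_units_of <- function(world, level) {
  spec <- world$spec
  idx <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  ctr <- cell_centroid(spec, idx$row, idx$col)
  pts <- structure(tibble::tibble(x = ctr[, 1], y = ctr[, 2], count = 1,
                                  dataset = "x"), crs_id = spec$crs_id)
  cl <- classify_points(pts, travel_time_grid(matrix(0, spec$n_rows,
                                                     spec$n_cols), spec),
                        world$admin_units, levels = level)
  matrix(cl[[paste0("admin", level, "_id")]], spec$n_rows, spec$n_cols)
}
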