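test_that("worlds are reproducible and conserve the configured population", {
  w1 <- make_world(small_config(), seed = 11)
  w2 <- make_world(small_config(), seed = 11)
  expect_identical(w1$landcover$values, w2$landcover$values)
  expect_identical(w1$households, w2$households)
  expect_identical(w1$settlements$x, w2$settlements$x)
  expect_identical(w1$facilities, w2$facilities)
  w3 <- make_world(small_config(), seed = 12)
  expect_false(identical(w1$households, w3$households))

  expect_equal(sum(w1$households$weight), 6000)
  # landcover palette: open, low-speed, settlement, water all present
  expect_true(all(c(10L, 20L, 30L, 200L) %in% w1$landcover$values))
  # facilities sit at settlement centers, drawn without replacement
  expect_false(anyDuplicated(w1$facilities$settlement_id) > 0)
  # footprint cells are never water
  for (fp in w1$settlements$footprint)
    expect_false(any(w1$water_mask[fp]))
})

test_that("degenerate configurations fail explicitly", {
  expect_error(make_world(small_config(n_settlements = 0), seed = 1),
               "n_settlements")
  expect_error(make_world(small_config(n_facilities = 99), seed = 1),
               "n_facilities")
  expect_error(
    make_world(world_config(n_rows = 12, n_cols = 12, n_settlements = 30,
                            settlement_min_sep_cells = 6, n_facilities = 1),
               seed = 1),
    "too small")
})

test_that("every household belongs to exactly one admin unit per level", {
  w <- make_world(small_config(), seed = 5)
  for (lv in 1:2) {
    n_in <- rep(0L, nrow(w$households))
    units <- w$admin_units[w$admin_units$level == lv, ]
    for (j in seq_len(nrow(units))) {
      ring <- units$geometry[[j]]
      n_in <- n_in + (sp::point.in.polygon(w$households$x, w$households$y,
                                           ring[, 1], ring[, 2]) == 1)
    }
    # strict interior containment in exactly one unit (edge hits have
    # probability zero for continuous positions)
    expect_true(all(n_in == 1))
  }
  # level-2 areas sum to their level-1 parents
  a2 <- tapply(w$admin_units$area_km2[w$admin_units$level == 2],
               w$admin_units$parent_id[w$admin_units$level == 2], sum)
  a1 <- setNames(w$admin_units$area_km2[w$admin_units$level == 1],
                 w$admin_units$id[w$admin_units$level == 1])
  expect_equal(as.numeric(a2[names(a1)]), as.numeric(a1), tolerance = 1e-12)
})

test_that("allocation schemes preserve census-unit totals exactly", {
  w <- make_world(small_config(), seed = 21)
  truth2 <- unit_truth(w, 2)
  for (kind in c("constrained", "unconstrained_uniform",
                 "unconstrained_covariate")) {
    pop <- suppressWarnings(
      allocate_population(w, allocation_scheme(kind, kind,
                                               census_unit_level = 2)))
    expect_equal(sum(pop$values), 6000, tolerance = 1e-9)
    # per-unit sums match the household tally of that unit
    pts <- classify_points(to_points(pop),
                           travel_time_grid(matrix(0, 60, 60), w$spec),
                           w$admin_units, levels = 2)
    got <- tapply(pts$count, pts$admin2_id, sum)
    expect_equal(got[names(truth2)], truth2, tolerance = 1e-9)
  }
})

test_that("constrained allocation lives on footprints; uniform spreads", {
  w <- make_world(small_config(), seed = 31)
  con <- allocate_population(
    w, allocation_scheme("con", "constrained", miss_rate = 0), seed = 1)
  uni <- allocate_population(
    w, allocation_scheme("uni", "unconstrained_uniform"), seed = 1)
  fp_cells <- do.call(rbind, w$settlements$footprint)
  fp <- matrix(FALSE, 60, 60)
  fp[fp_cells] <- TRUE
  # miss rate 0: support is exactly the detected footprints
  expect_true(all(con$values[!fp] == 0))
  expect_true(sum(con$values > 0) < sum(uni$values > 0))
  # footprints are a small minority of land cells here
  expect_lt(sum(fp), 0.2 * sum(!w$water_mask))
  # uniform is constant within a census unit on land cells
  units <- cell_units_of(w, 2)
  for (u in stats::na.omit(unique(as.vector(units)))) {
    v <- uni$values[units == u & !w$water_mask]
    if (length(v) > 1) expect_lt(diff(range(v)), 1e-9)
  }
})

test_that("all footprints missed falls back to uniform with a warning", {
  w <- make_world(small_config(), seed = 41)
  warns <- testthat::capture_warnings(
    pop <- allocate_population(
      w, allocation_scheme("con", "constrained", miss_rate = 0.95), seed = 2))
  expect_true(any(grepl("fell back", warns)))
  expect_equal(sum(pop$values), 6000, tolerance = 1e-9)
})

test_that("coarsening aggregates mass without loss", {
  w <- make_world(small_config(), seed = 51)
  pop <- allocate_population(w, allocation_scheme("uni", "unconstrained_uniform"),
                             coarsen = 4L)
  expect_equal(pop$spec$n_rows, 15L)
  expect_equal(pop$spec$cell_size, 400)
  expect_equal(sum(pop$values), 6000, tolerance = 1e-9)
  expect_error(allocate_population(w, allocation_scheme("u", "unconstrained_uniform"),
                                   coarsen = 7L), "divide")
})

test_that("true coverage matches manual enumeration on a hand fixture", {
  spec <- grid_spec(10, 10, cell_size = 100)
  # hand-made travel-time surface: minutes = column index; col 5 is water
  vals <- matrix(rep(1:10 * 10, each = 10), 10, 10)
  vals[, 5] <- NA
  tt <- travel_time_grid(vals, spec)
  ctr <- function(r, c) cell_centroid(spec, r, c)
  hh_cells <- rbind(c(1, 1), c(2, 1), c(3, 2), c(4, 3), c(5, 3),
                    c(6, 5), c(7, 7), c(8, 8), c(9, 9), c(10, 10))
  xy <- ctr(hh_cells[, 1], hh_cells[, 2])
  fake_world <- structure(
    list(spec = spec,
         households = tibble::tibble(x = xy[, 1], y = xy[, 2], weight = 1,
                                     settlement_id = 1)),
    class = "synthetic_world")
  # threshold 30 min: columns 1-3 qualify -> 5 of the 9 non-barrier
  cov <- true_coverage(fake_world, tt, 30)
  expect_equal(as.numeric(cov), 5 / 9)
  expect_equal(attr(cov, "pop_on_barrier"), 1)
  # all households reachable within 100 -> everything but the barrier one
  expect_equal(as.numeric(true_coverage(fake_world, tt, 100)), 1)
  # nothing reachable when no cell qualifies
  expect_equal(as.numeric(true_coverage(fake_world, tt, 5)), 0)
})

test_that("co-located facilities give full 30-min coverage", {
  cfg <- small_config(n_facilities = 6, settlement_spread_cells = 1)
  ww <- small_world_tt(seed = 61, config = cfg)
  expect_equal(as.numeric(true_coverage(ww$world, ww$tt, 30)), 1,
               tolerance = 1e-6)
})

test_that("constrained coverage tracks the household truth more closely", {
  cfg <- world_config(n_rows = 100, n_cols = 100, n_settlements = 8,
                      population_total = 10000,
                      settlement_min_sep_cells = 12, n_facilities = 2,
                      n_rivers = 1, n_forest_patches = 3,
                      forest_patch_radius_cells = 12)
  closer <- vapply(1:9, function(s) {
    ww <- small_world_tt(seed = 200 + s, config = cfg)
    w <- ww$world
    pc <- suppressWarnings(allocate_population(
      w, allocation_scheme("con", "constrained")))
    pu <- allocate_population(w, allocation_scheme("uni",
                                                   "unconstrained_uniform"))
    pts <- dplyr::bind_rows(
      classify_points(to_points(pc), ww$tt, w$admin_units),
      classify_points(to_points(pu), ww$tt, w$admin_units))
    cov <- coverage_stats(pts, thresholds = 30, levels = integer())
    truth <- 100 * as.numeric(true_coverage(w, ww$tt, 30))
    err <- abs(cov$coverage_pct - truth)
    err[cov$dataset == "con"] <= err[cov$dataset == "uni"]
  }, logical(1))
  expect_gt(mean(closer), 0.5)
})

test_that("world export round-trips through the documented formats", {
  d <- withr::local_tempdir()
  w <- make_world(small_config(), seed = 71)
  export_world(w, d)
  expect_true(all(file.exists(file.path(
    d, c("landcover.asc", "roads.geojson", "rivers.geojson",
         "facilities.geojson", "households.geojson", "admin1.geojson",
         "admin2.geojson", "manifest.yml")))))
  lc <- read_raster(file.path(d, "landcover.asc"))
  expect_equal(lc$values, w$landcover$values + 0)
  hh <- read_vectors(file.path(d, "households.geojson"), "point")
  expect_equal(nrow(hh), nrow(w$households))
  expect_equal(sum(hh$weight), 6000)
  mf <- yaml::read_yaml(file.path(d, "manifest.yml"))
  expect_equal(mf$seed, 71)
})
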