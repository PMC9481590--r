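make_line <- function(coords, class_code = 1L, crs = "EPSG:3395") {
  geo_features(list(coords), "line", crs_id = crs, class_code = class_code)
}

test_that("all-touched line rasterization covers the touched cells", {
  sc <- default_scenario()
  # horizontal line across a 1x5 grid row: all 5 cells
  gs <- grid_spec(1, 5, origin_x = 0, origin_y = 100, cell_size = 100)
  m <- rasterize_lines(make_line(cbind(c(0, 500), c(50, 50))), gs, sc)
  expect_equal(sum(!is.na(m)), 5)

  # diagonal corner-to-corner on 3x3: the 3 diagonal cells plus the 4
  # off-diagonal cells touched at the interior corner points (manual
  # enumeration: corners (100,100) and (200,200) each join 4 cells)
  gs3 <- grid_spec(3, 3, origin_x = 0, origin_y = 300, cell_size = 100)
  m3 <- rasterize_lines(make_line(cbind(c(0, 300), c(0, 300))), gs3, sc)
  got <- which(!is.na(m3), arr.ind = TRUE)
  expected <- rbind(c(3, 1), c(2, 2), c(1, 3),   # interior passes
                    c(2, 1), c(3, 2), c(1, 2), c(2, 3))  # corner touches
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(expected[, 1], expected[, 2]))

  # every rasterized cell genuinely lies near the segment
  gsr <- grid_spec(20, 20, cell_size = 100)
  seg <- cbind(c(130, 1870), c(240, 1630))
  mr <- rasterize_lines(make_line(seg), gsr, sc)
  hit <- which(!is.na(mr), arr.ind = TRUE)
  ctr <- cell_centroid(gsr, hit[, 1], hit[, 2])
  d <- vapply(seq_len(nrow(ctr)), function(i) {
    p <- ctr[i, ]; a <- seg[1, ]; b <- seg[2, ]
    t <- pmin(1, pmax(0, sum((p - a) * (b - a)) / sum((b - a)^2)))
    sqrt(sum((a + t * (b - a) - p)^2))
  }, numeric(1))
  expect_true(all(d <= 100 * sqrt(2) / 2 + 1e-9))
  # and the densely sampled path is a subset of the rasterized cells
  tt <- seq(0, 1, length.out = 2000)
  samp <- point_to_cell(gsr, seg[1, 1] + tt * diff(seg[, 1]),
                        seg[1, 2] + tt * diff(seg[, 2]))
  expect_true(all(paste(samp$row, samp$col) %in% paste(hit[, 1], hit[, 2])))
})

test_that("crossing roads resolve to the faster class; CRS mismatch errors", {
  sc <- default_scenario()
  gs <- grid_spec(3, 3, cell_size = 100)
  crossing <- geo_features(
    list(cbind(c(0, 300), c(150, 150)),   # primary, horizontal
         cbind(c(150, 150), c(0, 300))),  # tertiary, vertical
    "line", crs_id = "EPSG:3395", class_code = c(1L, 3L))
  m <- rasterize_lines(crossing, gs, sc)
  expect_equal(m[2, 2], 1L)  # 80 km/h beats 30 km/h in the shared cell
  expect_gt(attr(m, "n_conflicts"), 0)

  wrong <- geo_features(list(cbind(c(0, 1), c(0, 1))), "line",
                        crs_id = "EPSG:32736", class_code = 1L)
  expect_error(rasterize_lines(wrong, gs, sc), "CRS mismatch")
})

test_that("barrier rasterization: polygons by centroid, rivers all-touched", {
  gs <- grid_spec(4, 4, origin_x = 0, origin_y = 400, cell_size = 100)
  lake <- geo_features(list(cbind(c(100, 300, 300, 100, 100),
                                  c(100, 100, 300, 300, 100))), "polygon")
  mask <- rasterize_barriers(NULL, lake, gs)
  expect_equal(sum(mask), 4)  # the 2x2 block of covered centroids
  expect_true(all(mask[2:3, 2:3]))

  river <- geo_features(list(cbind(c(150, 150), c(400, 0))), "line")
  rmask <- rasterize_barriers(river, NULL, gs)
  expect_equal(sum(rmask), 4)          # one column of cells
  expect_true(all(rmask[, 2]))

  empty <- rasterize_barriers(NULL, NULL, gs)
  expect_false(any(empty))
})

test_that("merge priority is road > barrier > landcover (bridge rule)", {
  gs <- grid_spec(1, 3, cell_size = 100)
  lc <- geo_grid(matrix(20L, 1, 3), gs)              # forest everywhere
  roads <- matrix(c(1L, 1L, NA), 1, 3)               # road over cells 1-2
  barrier <- matrix(c(TRUE, TRUE, FALSE), 1, 3)      # water under cells 1-2
  m <- merge_layers(lc, roads, barrier)
  expect_equal(m$classes[1, ], c(1L, 1L, 20L))
  expect_equal(m$provenance[1, ], c("road", "road", "landcover"))

  m2 <- merge_layers(lc, NULL, matrix(c(TRUE, FALSE, FALSE), 1, 3))
  expect_equal(m2$classes[1, 1], 200L)
  expect_equal(m2$provenance[1, 1], "barrier")

  lc_hole <- geo_grid(matrix(c(NA, 20L, 20L), 1, 3), gs)
  expect_error(merge_layers(lc_hole), "complete")
})

test_that("scenario resolution fills from fallback and reports strays", {
  sc <- default_scenario()
  expect_equal(as.data.frame(resolve_scenario(sc, c(1L, 10L, 200L))),
               as.data.frame(sc), ignore_attr = TRUE)
  expect_message(filled <- resolve_scenario(sc, c(1L, 4L)), "fallback")
  expect_equal(filled$speed_kmh[filled$class_code == 4L], 70)
  expect_equal(attr(filled, "filled"), 4L)
  expect_error(resolve_scenario(sc, c(1L, 999L)), "999")
})

test_that("crossing times follow cell size over speed", {
  gs <- grid_spec(2, 2, cell_size = 100)
  lc <- geo_grid(matrix(c(1L, 10L, 200L, 20L), 2, 2), gs)
  fr <- build_friction(merge_layers(lc), default_scenario())
  expect_equal(fr$values[1, 1], 0.1 / 80 * 60)  # 80 km/h road: 0.075 min
  expect_equal(fr$values[2, 1], 1.2)            # 5 km/h walk: 1.2 min
  expect_true(is.na(fr$values[1, 2]))           # waterbody masked
  expect_true(fr$barrier[1, 2])

  # scale property: doubling cell size doubles every finite time
  gs2 <- grid_spec(2, 2, cell_size = 200)
  fr2 <- build_friction(merge_layers(geo_grid(lc$values, gs2)),
                        default_scenario())
  expect_equal(fr2$values[!fr2$barrier], 2 * fr$values[!fr$barrier])

  # monotonicity: raising a speed never increases any crossing time
  faster <- default_scenario()
  faster$speed_kmh[faster$class_code == 20L] <- 4
  fr3 <- build_friction(merge_layers(lc), as_scenario_table(faster))
  expect_true(all(fr3$values <= fr$values, na.rm = TRUE))
})

test_that("no road cell ends up in the barrier mask on a full world", {
  ww <- small_world_tt(seed = 3)
  sc <- default_scenario()
  roads <- rasterize_lines(ww$world$roads, ww$world$spec, sc)
  merged <- merge_layers(ww$world$landcover, roads, ww$world$water_mask)
  fr <- build_friction(merged, sc)
  expect_false(any(fr$barrier[merged$provenance == "road"]))
  expect_true(all(fr$values[!fr$barrier] > 0))
})
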