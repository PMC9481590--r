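#' Seed health facilities onto the friction grid
#'
#' Each facility point is mapped to its containing cell. A facility whose
#' cell is impassable (water/nodata) is snapped to the nearest passable
#' cell within `snap_radius_cells` (Euclidean cell distance, ties broken
#' in row-major order); one that cannot be snapped is dropped and
#' counted, as are facilities falling outside the grid after clipping.
#'
#' @param facilities A point [geo_features()] collection, or a data frame
#'   with `x`, `y` columns.
#' @param friction A `friction_grid`.
#' @param snap_radius_cells Maximum snap displacement in cells (>= 0).
#' @return A `facility_seeds` tibble (`id`, `x`, `y`, `row`, `col`,
#'   `snap_cells`) with attributes `n_dropped` and `spec`. Zero seeded
#'   facilities is an error: the travel-time computation needs sources.
#' @export
seed_facilities <- function(facilities, friction, snap_radius_cells = 5) {
  stopifnot(inherits(friction, "friction_grid"), snap_radius_cells >= 0)
  spec <- friction$spec
  if (inherits(facilities, "geo_features")) {
    check_crs(facilities, spec)
    xy <- do.call(rbind, facilities$geometry)
    pts <- tibble::tibble(x = xy[, 1], y = xy[, 2])
  } else {
    pts <- tibble::as_tibble(facilities)[c("x", "y")]
  }
  pts$id <- seq_len(nrow(pts))
  cells <- point_to_cell(spec, pts$x, pts$y)
  outside <- is.na(cells$row)
  if (any(outside))
    message(sum(outside), " facility(ies) outside the grid dropped")
  barrier <- friction$barrier
  res <- vector("list", nrow(pts))
  n_dropped <- sum(outside)
  r_int <- ceiling(snap_radius_cells)
  for (j in which(!outside)) {
    r0 <- cells$row[j]; c0 <- cells$col[j]
    if (!barrier[r0, c0]) {
      res[[j]] <- c(r0, c0, 0)
      next
    }
    # spiral-free exhaustive search in the snap window; fine at radius ~5
    win <- expand.grid(row = max(1, r0 - r_int):min(spec$n_rows, r0 + r_int),
                       col = max(1, c0 - r_int):min(spec$n_cols, c0 + r_int))
    d <- sqrt((win$row - r0)^2 + (win$col - c0)^2)
    ok <- d <= snap_radius_cells & !barrier[cbind(win$row, win$col)] & d > 0
    if (!any(ok)) {
      n_dropped <- n_dropped + 1L
      message("facility ", pts$id[j], " unsnappable within ",
              snap_radius_cells, " cells; dropped")
      next
    }
    cand <- win[ok, , drop = FALSE]
    dd <- d[ok]
    ord <- order(dd, cand$row, cand$col)  # ties: row-major
    res[[j]] <- c(cand$row[ord[1]], cand$col[ord[1]], dd[ord[1]])
    if (dd[ord[1]] > 0)
      message("facility ", pts$id[j], " snapped ",
              format(dd[ord[1]], digits = 3), " cells off water")
  }
  seeded <- !vapply(res, is.null, logical(1))
  if (!any(seeded))
    stop("no facilities could be seeded onto the friction grid", call. = FALSE)
  m <- do.call(rbind, res[seeded])
  out <- tibble::tibble(id = pts$id[seeded], x = pts$x[seeded], y = pts$y[seeded],
                        row = as.integer(m[, 1]), col = as.integer(m[, 2]),
                        snap_cells = m[, 3])
  structure(out, class = c("facility_seeds", class(out)),
            n_dropped = n_dropped, spec = spec)
}

#' Travel time to the nearest facility (eight-directional least cost)
#'
#' Exact multi-source shortest path over the 8-connected lattice graph.
#' The edge weight between adjacent passable cells is the mean of their
#' crossing times, multiplied by sqrt(2) for diagonal neighbours — the
#' standard isotropic cost-surface convention. Barrier cells are excluded
#' from the graph; facility cells start at zero; each cell gets the exact
#' minimum over all facilities. Cells with finite friction but no
#' barrier-free path to any facility come back as `Inf` (unreachable),
#' distinct from barrier `NA`.
#'
#' @param friction A `friction_grid`.
#' @param seeds A `facility_seeds` table from [seed_facilities()].
#' @return A `travel_time_grid` (a [geo_grid()] of minutes; `Inf` =
#'   unreachable, `NA` = barrier).
#' @examples
#' fr <- friction_grid(matrix(1, 5, 5), grid_spec(5, 5, cell_size = 100))
#' sd <- seed_facilities(data.frame(x = 50, y = 450), fr)
#' tt <- least_cost_travel_time(fr, sd)
#' tt$values[5, 5]  # octile metric: 4 + (sqrt(2)-1)*4
#' @export
least_cost_travel_time <- function(friction, seeds) {
  stopifnot(inherits(friction, "friction_grid"), nrow(seeds) >= 1)
  stop_if_grid_mismatch(friction$spec, attr(seeds, "spec"))
  spec <- friction$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  t <- friction$values
  pass <- !friction$barrier
  n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)

  shift_pairs <- function(dr, dc, mult) {
    if (dc >= 0) {
      a <- idx[seq_len(nr - dr), seq_len(nc - dc), drop = FALSE]
      b <- idx[seq_len(nr - dr) + dr, seq_len(nc - dc) + dc, drop = FALSE]
    } else {
      a <- idx[seq_len(nr - dr), seq(1 - dc, nc), drop = FALSE]
      b <- idx[seq_len(nr - dr) + dr, seq(1, nc + dc), drop = FALSE]
    }
    keep <- pass[a] & pass[b]
    list(a = a[keep], b = b[keep],
         w = (t[a[keep]] + t[b[keep]]) / 2 * mult)
  }
  prs <- list(shift_pairs(0L, 1L, 1), shift_pairs(1L, 0L, 1),
              shift_pairs(1L, 1L, sqrt(2)), shift_pairs(1L, -1L, sqrt(2)))
  a <- unlist(lapply(prs, `[[`, "a"))
  b <- unlist(lapply(prs, `[[`, "b"))
  w <- unlist(lapply(prs, `[[`, "w"))
  seed_ids <- unique(idx[cbind(seeds$row, seeds$col)])
  super <- n + 1L
  edges <- rbind(c(a, rep(super, length(seed_ids))),
                 c(b, seed_ids))
  g <- igraph::make_graph(as.vector(edges), n = super, directed = FALSE)
  weights <- c(w, rep(0, length(seed_ids)))
  d <- igraph::distances(g, v = super, weights = weights,
                         algorithm = "dijkstra")[1, seq_len(n)]
  vals <- matrix(d, nr, nc)
  vals[!pass] <- NA_real_
  travel_time_grid(vals, spec, barrier = !pass, seeds = seeds)
}

#' Construct a travel-time grid
#'
#' @param values Matrix of minutes to the nearest facility; `Inf` marks
#'   finite-friction cells with no path, `NA` marks barrier cells.
#' @param spec A [grid_spec()].
#' @param barrier Logical barrier mask.
#' @param seeds Optional `facility_seeds` used to produce the surface.
#' @return A `travel_time_grid`.
#' @export
travel_time_grid <- function(values, spec, barrier = is.na(values),
                             seeds = NULL) {
  g <- geo_grid(values, spec)
  stopifnot(identical(dim(barrier), dim(values)))
  if (any(values[!barrier] < 0, na.rm = TRUE))
    stop("negative travel time", call. = FALSE)
  g$barrier <- barrier
  g$seeds <- seeds
  class(g) <- c("travel_time_grid", class(g))
  g
}

#' Per-cell status of a travel-time grid
#'
#' @param tt A `travel_time_grid`.
#' @return Character matrix: `"finite"`, `"unreachable"` or `"barrier"`.
#' @export
tt_status <- function(tt) {
  s <- matrix("finite", tt$spec$n_rows, tt$spec$n_cols)
  s[is.infinite(tt$values)] <- "unreachable"
  s[tt$barrier] <- "barrier"
  s
}
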