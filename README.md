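# geoaccess

Geographic accessibility of health facilities, and how much the answer
depends on which gridded population dataset you use.

## The problem

*Accessibility coverage* is the share of a population able to reach its
nearest health facility within a travel-time threshold *T*:

```
coverage(T) = 100 · Σ pop(p) [t(p) ≤ T] / Σ pop(p)
```

summed over population points *p* not lying on barriers, where *t(p)* is
the least-cost travel time of the point's grid cell. Travel time is
computed on a **friction surface** *f* (minutes to cross one cell),
assembled from landcover (walking speeds), roads (motorized speeds,
with priority over everything — a road over a river is a bridge) and
water barriers (impassable). The travel-time surface is the exact
multi-source shortest path on the 8-connected lattice with edge weights

```
w(a, b) = (f_a + f_b) / 2        orthogonal neighbours
w(a, b) = (f_a + f_b) / 2 · √2   diagonal neighbours
```

minimized over all facilities (isotropic: no slope correction).

Gridded population datasets put *pop(p)* in very different places:
**constrained** products restrict census totals to detected settlement
footprints, **unconstrained** ones spread them over all land of a
census unit, and dasymetric products sit in between. `geoaccess`
quantifies how that choice propagates into coverage statistics: it
computes per-admin-unit coverage tables for any number of population
rasters, pairwise difference matrices, per-unit mean disagreement, and
the association between census-unit size and disagreement. A built-in
synthetic-world generator (clustered settlements with household-level
ground truth, spanning road network, river barriers, nested admin
units, and the three allocation families above) makes every statistic
checkable against a known truth.

## Worked example

```r
library(geoaccess)
library(dplyr)

w  <- make_world(world_config(), seed = 1)   # 16x16 km, 12 settlements,
w                                            # 20,000 people, 3 facilities
#> <synthetic_world> 160x160@100m, 12 settlements, 4000 households (20000 people),
#>   3 facilities, 11 roads, 1 rivers, 20 admin units (L1 4 / L2 16)

fr <- world_friction(w)                      # merged classes -> minutes/cell
tt <- least_cost_travel_time(fr, seed_facilities(w$facilities, fr))
tt
#> <travel_time_grid> 160x160@100m CRS EPSG:3395
#>   finite cells: 25388  range [0, 107.296]  sum 748228

pops <- list(
  allocate_population(w, allocation_scheme("constrained", "constrained")),
  allocate_population(w, allocation_scheme("uniform", "unconstrained_uniform")))
pts <- bind_rows(lapply(pops, \(p) classify_points(to_points(p), tt, w$admin_units)))
cov <- coverage_stats(pts, thresholds = c(30, 60, 120))
filter(cov, admin_level == 0) |>
  select(dataset, threshold_min, pop_covered, coverage_pct)
#>   dataset     threshold_min pop_covered coverage_pct
#> 1 constrained            30      19799.         99.0
#> 2 constrained            60      19995         100.0
#> 3 constrained           120      20000         100
#> 4 uniform                30      15390.         77.0
#> 5 uniform                60      19422.         97.1
#> 6 uniform               120      20000         100
```

The same 20,000 people, the same facilities, the same travel-time
surface — but spreading the census totals uniformly over each census
unit instead of constraining them to settlement footprints drops
30-minute coverage from 99.0% to 77.0% (the household-level ground
truth is 100.0%): unconstrained spreading places people in remote land
far from facilities, deflating coverage. `pairwise_diff(cov, 30)`
reports the 22.0 pp gap; `barrier_report()` tallies population falling
on water.

Disagreement between datasets grows with the size of the census unit
population is released in. Stacking a coarse-release run (allocation
within level-1 units) on a fine-release run (level-2) and correlating
per-unit disagreement with unit area:

```r
ud <- bind_rows(lapply(1:2, function(lev) {
  pc <- allocate_population(w,
    allocation_scheme("constrained", "constrained", census_unit_level = lev))
  pu <- allocate_population(w,
    allocation_scheme("uniform", "unconstrained_uniform", census_unit_level = lev))
  pts <- bind_rows(classify_points(to_points(pc), tt, w$admin_units),
                   classify_points(to_points(pu), tt, w$admin_units))
  average_unit_diff(coverage_stats(pts, thresholds = c(30, 60), levels = lev),
                    60, lev, w$admin_units)
}))
glance(size_association(ud))
#>     rho n_units degenerate
#> 1 0.153      14 FALSE
```

`autoplot()` methods exist for grids, travel-time surfaces, pairwise
matrices and unit-diff summaries; `plot_coverage_curves()` draws
coverage against threshold per dataset.

## Command line

```sh
Rscript inst/cli/geoaccess.R run-all \
    --config inst/extdata/demo_config.yml --seed 7 --out demo_out/
```

Subcommands `simulate`, `friction`, `traveltime`, `coverage`,
`compare` run the stages independently; outputs are `coverage.csv`
(`dataset,admin_level,admin_id,threshold_min,pop_covered,pop_total,
coverage_pct,pop_on_barrier,pop_unreachable`), `pairwise.csv`,
`unit_diff.csv`, `barrier.csv`, plus the rasters and a run log.
Re-running a stage with the same config and seed is byte-identical.

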