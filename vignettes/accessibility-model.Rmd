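---
title: "Modelling healthcare accessibility across gridded population datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling healthcare accessibility across gridded population datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(geoaccess)
library(dplyr)
```

## The problem

Accessibility coverage — the share of a population able to reach its
nearest health facility within a travel-time threshold — is a standard
indicator behind health-system planning and global monitoring targets.
Computing it requires three ingredients: facility locations, a model of
travel time across the landscape, and a gridded population dataset. The
last ingredient is not unique: half a dozen widely used gridded
population products exist, and they disagree, because they redistribute
census totals into grid cells in fundamentally different ways. Products
that *constrain* population to detected settlement footprints put people
where buildings are; *unconstrained* products spread census-unit totals
over all land, deserts and forests included. Since facilities stand
where people cluster, the choice of product systematically shifts
coverage estimates: spreading population into remote land inflates
travel times and deflates coverage, most strongly in large, sparsely
populated administrative units whose census totals are released at a
coarse scale.

`geoaccess` implements the full pipeline for quantifying that effect,
with a synthetic-world generator standing in for the continental input
stack (landcover rasters, road and river vectors, facility inventories,
admin boundaries, population products), so every statistic can be
checked against a known ground truth.

## The accessibility model

Travel time is computed on a **friction surface**: a raster whose cell
value is the time (minutes) to cross one cell orthogonally. The surface
is assembled from three layers with a strict priority:

1. **roads** (rasterized all-touched, fastest class wins where classes
   cross) — motorized speeds;
2. **barriers** (river lines all-touched, water polygons by cell
   centroid) — impassable, *unless a road crosses over* (the bridge
   rule: a rasterized road cell keeps its road class even over water);
3. **landcover** — walking speeds per class.

A travel scenario maps each class code to a speed; classes missing from
a scenario are filled from a table of average road-class speeds, and a
class in neither table is an error. Crossing time is
`(cell_size/1000) / speed_kmh * 60` minutes.

Travel time to the nearest facility is then the exact multi-source
shortest path on the 8-connected lattice: the edge weight between
adjacent passable cells `a`, `b` is `(t_a + t_b)/2`, multiplied by
`sqrt(2)` for diagonal neighbours — the standard isotropic cost-surface
convention (the AccessMod / `r.cost` family). We fix this transition
rule explicitly because the literature often cites "the
eight-directional algorithm" without writing it down. The model is
isotropic: no slope correction, no direction-dependent speeds. On
uniform friction the resulting metric is exactly the octile distance
`t * (max(|dx|,|dy|) + (sqrt(2)-1) * min(|dx|,|dy|))`, which the test
suite verifies, alongside cell-exact agreement with an independent
label-correcting shortest-path oracle on randomized surfaces.

Facilities falling on water are snapped to the nearest passable cell
within a 5-cell radius (Euclidean cell distance, row-major
tie-breaking); unsnappable or out-of-grid facilities are dropped with a
logged count. Cells with no barrier-free path to any facility are
**unreachable** — reported distinctly from barrier cells, kept in
coverage denominators, never covered.

## Population handling

Population rasters are never resampled. Each dataset is harmonized
(clipped to the region, with per-level-2-unit multiplicative rescaling
restoring the original unit totals exactly — "mass preservation") and
then converted to **centroid points**, one per positive cell at the
dataset's native resolution. Each point is annotated with the travel
time of its containing cell and its admin units (point-in-polygon,
first unit in stable id order on boundary ties). Coverage statistics
are then plain zonal sums over points:

* `pop_covered(threshold)` — points with finite travel time at or below
  the threshold;
* `pop_total` — all points except those on barriers or out of region
  (unreachable points stay in the denominator);
* `coverage_pct = 100 * pop_covered / pop_total`, undefined (not 0%)
  where a unit has no non-barrier population.

The barrier-exclusion denominator is the convention under which the
published continental summary tables are internally consistent
(covered/total reproduces the printed percentages at one-decimal
rounding), and the test suite re-derives all 36 such ratios. Rescaling
unit totals multiplicatively — rather than adding a uniform offset —
preserves the within-unit spatial pattern and, crucially, the zero
cells of constrained datasets; the per-unit factors are logged. A unit
whose processed total collapses to zero has its original total respread
uniformly over its land cells, with a warning, mirroring the fallback
behaviour of real products.

## The synthetic world

`make_world()` generates the full input stack with known ground truth:

* **Settlements and households** — a parent–child clustered process:
  settlement centers drawn with a minimum separation (default 1.5 km)
  on non-water land, household counts per settlement lognormal,
  household positions Gaussian around their center (default dispersion
  250 m). Households carry equal weights summing *exactly* to the
  configured population. The settlement **footprint** is the set of
  cells actually containing households.
* **Roads** — the minimum spanning tree over settlement centers (which
  contains every settlement's nearest-neighbour link), with faster
  classes on longer trunk edges.
* **Rivers** — meandering polylines crossing the domain; barriers
  except where a road bridges them.
* **Admin units** — a cell-aligned guillotine partition: level-1
  rectangles of random unequal extents, each subdivided into level-2
  rectangles. Areas therefore vary several-fold, and every cell (and
  household) belongs to exactly one unit per level.
* **Facilities** — a subset of settlement centers drawn without
  replacement.

All randomness flows from one seed through a documented splitting rule
(one substream per stage: terrain, rivers, admin, settlements, roads,
facilities), so stages are independently reproducible and adding a
stage never perturbs earlier ones.

Three **allocation schemes** emulate the product families. Each
redistributes the *true* per-census-unit household totals within the
unit — never across — so unit totals are preserved exactly by
construction:

| scheme | weight within census unit | emulates |
|---|---|---|
| `constrained` | true household mass on *detected* footprint cells; each settlement's footprint is missed with probability `miss_rate` (default 0.1) | building-footprint products |
| `unconstrained_uniform` | equal on every non-water cell | areal-weighting products |
| `unconstrained_covariate` | Gaussian-smoothed settlement indicator (sigma 4 cells) times lognormal noise (sd 0.5) | dasymetric products with ancillary covariates |

The covariate defaults were chosen to make that scheme intermediate
between the other two. A constrained unit whose footprints are all
missed falls back to uniform spreading with a warning. `coarsen`
aggregates an allocation to a coarser lattice (e.g. 1-km cells), which
is how coarse products end up placing centroid mass on barrier cells.
Census-release coarseness itself is modeled by allocating within
level-1 (coarse) versus level-2 (fine) units.

## Study conditions and what they show

The generator defaults are the package's study conditions: a 16 × 16 km
region at 100-m resolution (25,600 cells), 12 settlements, 20,000
people in 4,000 households, 3 facilities, one river, five forest
patches, walking at 5 km/h (2 km/h under canopy) and 30–80 km/h on
roads. These were set so the region is genuinely sparse — substantial
land lies beyond the 30- and 60-minute catchments on foot — because
that is the regime in which population products disagree; in a dense,
well-roaded region all schemes converge and the comparison is
uninformative. At these conditions the acceptance suite reproduces,
over 20 independent worlds, the qualitative findings the pipeline
exists to quantify: constrained allocation yields higher coverage than
uniform unconstrained allocation at 30 and 60 minutes (the constrained
estimate also tracks the household ground truth more closely), and
per-unit disagreement between schemes grows with census-unit size
(positive Spearman correlation between unit area and mean pairwise
coverage difference, stacking coarse- and fine-release runs).

What passing these tests does **not** show: fidelity to any named real
product (the schemes operationalize redistribution families, not
algorithms — no random-forest dasymetrics, no night-lights weighting),
realistic travel behaviour (single scenario, no seasonality, no
cross-border travel, no slope), or real-world magnitudes of population
and area. The synthetic world has rectangular admin units, straight
roads and equal household weights; real inputs have none of these.

## Numerical choices and edge cases

* Cell convention: (row 1, col 1) at the north-west corner; half-open
  cell extents, so every point maps to at most one cell; centroids
  invert exactly.
* One projected metric CRS per run; mixed grids or CRSs are refused,
  never silently resampled or reprojected.
* Line rasterization is all-touched over *closed* cells (a corner graze
  counts), so 100-m roads stay 8-connected across diagonals; crossing
  classes resolve to the faster class (conservative for connectivity).
* Friction is stored direction-free (minutes per orthogonal crossing);
  all diagonal geometry lives in the shortest-path edge weights.
* Shortest paths use an exact priority-queue computation (via igraph)
  from a zero-weight super-source joined to all facility cells; results
  are deterministic and oracle-checkable to 1e-9 minutes.
* Coverage percentages are full precision internally and rounded to one
  decimal only at CSV serialization.
* Degenerate inputs fail loudly and early: zero settlements, domains
  too small for the requested separation, thresholds out of order,
  scenario classes without speeds, all facilities unsnappable.

## Problem sizes

The test suite runs its functional checks on 60 × 60-cell worlds and
the acceptance checks at the full 160 × 160 study conditions (20 worlds
for the directional properties; 200 randomized grids up to 50 × 50 for
the shortest-path oracle; a 101 × 101 grid for the octile closed form).
`scripts/acceptance.R` re-runs the whole pipeline at the study
conditions from a single command-line seed.

## Known limitations

Travel time is sampled at the population point, so a coarse dataset's
single centroid stands for its whole cell — the price of refusing to
resample population, shared with the analyses this package models.
Rank correlations on small worlds use few units (20 per world); the
acceptance property therefore aggregates direction over many seeds
rather than asserting a correlation magnitude. The CLI serializes
rasters as Esri ASCII grids with a `.prj` sidecar; these are plain text
and portable, but large worlds produce large files.
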