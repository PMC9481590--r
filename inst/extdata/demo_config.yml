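# Small demo run: a 6 x 6 km synthetic region at 100-m resolution with
# three population datasets (one per allocation family). Finishes in a
# few seconds; see the methods vignette for the full-size defaults.
world:
  n_rows: 60
  n_cols: 60
  cell_size: 100
  n_settlements: 8
  population_total: 8000
  household_size: 5
  settlement_min_sep_cells: 8
  n_facilities: 3
  n_rivers: 1
  n_forest_patches: 2
  forest_patch_radius_cells: 10
thresholds_min: [30, 60, 90, 120, 150, 180]
admin_levels: [1, 2]
snap_radius_cells: 5
compare_level: 2
seed: 7
schemes:
  - name: constrained
    kind: constrained
    census_unit_level: 2
    miss_rate: 0.1
  - name: uniform
    kind: unconstrained_uniform
    census_unit_level: 2
  - name: covariate
    kind: unconstrained_covariate
    census_unit_level: 2
    noise_scale: 0.5
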