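# Demonstration pipeline configuration: a compact synthetic town with a
# 200-child cohort, all seven intensity measures at the six study
# distances. Run with:
#   Rscript inst/cli/kernelhoods.R run --config inst/extdata/demo_config.yaml
out_dir: demo_run
seed: 1
city:
  window_width_m: 3000
  window_height_m: 3000
  grid_spacing_m: 150
  edge_dropout_frac: 0.10
  density_peak_residents_km2: 4000
  density_floor_residents_km2: 200
  anisotropy_ratio: 1.5
cohort:
  n_children: 200
  frac_school_age: 0.75
  frac_girls: 0.515
  gamma_shape: 8
exposure:
  distances: [500, 750, 1000, 1250, 1500, 2000]
  measures: [simple, fixed, fixed_adaptive, mse_cv, mse_cv_adaptive, lscv, lscv_adaptive]
  buffer_m: 25
  cell_size_m: 25
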