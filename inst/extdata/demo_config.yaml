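# Demo scenario for the full pipeline: a 96 x 96 cell landscape at 10 m
# with the default nine-class mosaic, the default disturbance schedule
# (background fires/harvests/low-severity events 1988-2020 plus a 2022
# war-damage pulse), moderate observation noise and one anomalous
# fire-weather year.
scenario:
  grid_rows: 96
  grid_cols: 96
  resolution_m: 10
  trajectory_noise_sd: 0.03
  weather_anomaly_years: [2014]
  seed: 42
classify:
  ntree: 300
segment:
  max_segments: 6
  rmse_improvement_tol: 0.01
attribute:
  ntree: 300
  holdout_fraction: 0.2
hazard:
  adjacency_distance_m: 30
  min_supporting_patch_ha: 1
  resample_factor: 3
area:
  n_reference: 500
  aggregation: linear
anomaly:
  disturbance_threshold: 3
  weather_threshold: 2
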