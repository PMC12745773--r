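# Example heatmort pipeline configuration (see read_pipeline_config()).
master_seed: 7
output_dir: heatmort_out
n_samples: 500
generator:
  n_departments: 10
  years: [1980, 2012]
  noise: poisson
  adaptation:
    year: 2004
    factor: 0.5
event:
  year: 2003
  start_cday: 214
  end_cday: 227
  peak_uplift: 8
  profile: triangular
periods:
  pre: [1980, 2002]
  post: [2004, 2012]
scenarios:
  "GMT+0.0": -1.2
  "GMT+1.5": 0.9
  "GMT+2.0": 1.5
model:
  poly_order: 4
  n_lags: 5
  compounding: previous_level
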