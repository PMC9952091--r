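# Example pipeline configuration for run_pipeline(read_pipeline_config(...))
# Units: micrometres and minutes throughout.
synth:
  n_cells: 60
  duration: 1440        # 24 h movie
  dt: 4                 # frame interval
  field_size: [560, 560]
  D_true: 0.25          # random-migration diffusivity, um^2/min
  v_true: [0.0, 0.0]    # directed-motion velocity, um/min
  short_period: 40      # centre of the 28-60 min band
  long_period: 108      # centre of the 92-124 min band
  burst_lag: 20
  burst_gain: 0.25
  rng_seed: 1
seed: 1
bootstrap_B: 200
gradient_axis: [1, 0]
vsi_h: 25
vsi_sigma: 50
vsi_dt_agg: 20
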