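seed: 42
out_dir: desimrm_demo_run
phantom:
  kind: tumor_stroma
  params:
    width_um: 1500
    height_um: 600
    grid_um: 50
    n_blobs: 3
    blob_um: 400
acquisition:
  transitions: auto
  dwell_ms: 9
  stage_speed_um_s: 500
  line_spacing_um: 100
  line_length_um: 1500
  n_lines: 6
simulate:
  jitter_px_max: 2
  noise: true
align:
  enabled: true
  max_shift_px: 5
  reference: sum_of_channels
roi_stats:
  enabled: true
  k: 3
  size_px: 4
classify:
  enabled: true
  method: mmc
  k_folds: 5
  scheme: random_subset
report:
  enabled: true
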