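# Demo configuration for run_pipeline(): a small synthetic feeding-fasting
# experiment with three conditions, imaged ROIs, rhythm fitting, synchrony
# and a JTK transcriptome scan. Run with:
#   run_pipeline(system.file("extdata", "demo-config.yaml", package = "circaflux"),
#                out_dir = "demo_run")
seed: 1
stages: [simulate, imaging, rhythms, sync, jtk]
simulate:
  n_traces: 4
  days: 6
  conditions:
    HL: {phase0_h: 0}
    LH: {phase0_h: 12}
    HH: {phase0_h: 0, amplitude: 60}
imaging:
  roi_size_px: 16
  frame_shape: [48, 64]
  days: 4
  spike_rate: 2
  spike_amp: 2000
rhythms:
  detrend_window_h: 24
  period_bounds_h: [16, 32]
sync:
  t_start_h: 12
jtk:
  n_genes: 200
  frac_rhythmic: 0.3
  p_max: 0.01
  amp_min: 10
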