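# Small demonstration scenario for run_pipeline(): a 6-wave accelerated
# longitudinal design at toy size. All blocks are optional; omitted fields
# fall back to package defaults.
task:
  sampling_rate_hz: 300
  gap_lead_ms: 200
  isi_range_ms: [600, 700]
  peripheral_eccentricity_deg: 20.8
  peripheral_timeout_ms: 2000
cohort:
  n_per_wave: [6, 6, 4, 3, 4, 3]
  retention_prob: [0.6, 0.5, 0.3, 0.0, 0.3]
profile:
  noise_rms_deg: 0.5
  data_loss_prob: 0.15
  premature_prob: 0.05
  wrong_dir_prob: 0.05
  no_move_prob: 0.05
questionnaire:
  rho: 0.3
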