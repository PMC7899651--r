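# Demo pipeline configuration: two small groups recorded in a retrieval-style
# session. Full schema documented in FORMATS.md.
seed: 42
protocol:
  kind: RETRIEVAL
classifier:
  bin_width: 0.1
  response_window: 0.5
  n_baseline_bins: 10
  z_threshold: 1.96
  min_supra_bins: 2
  sd_denominator: n-1
simulation:
  groups:
    - group: control
      n_units: 12
      rate_mean_hz: 4
      rate_sdlog: 0.5
      frac_cs_on: 0.5
      frac_freeze_off: 0.25
      cs_multiplier: 4
      freeze_multiplier: 4
    - group: inhibited
      n_units: 12
      rate_mean_hz: 4
      rate_sdlog: 0.5
      frac_cs_on: 0.0
      frac_freeze_off: 0.0
      cs_multiplier: 1
      freeze_multiplier: 1
  behavior:
    move_to_freeze_cs: 0.10
    freeze_to_move_cs: 0.02
    move_to_freeze_out: 0.02
    freeze_to_move_out: 0.10
    min_bout: 1
sampling:
  sample_interval: 5
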