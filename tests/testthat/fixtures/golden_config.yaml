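# Tiny fixed cohort used for the frozen-output regression check.
seed: 7
protocol:
  kind: RETRIEVAL
simulation:
  groups:
    - group: demo
      n_units: 4
      rate_mean_hz: 4
      rate_sdlog: 0.3
      frac_cs_on: 0.5
      frac_freeze_off: 0.25
      cs_multiplier: 5
      freeze_multiplier: 5
  behavior:
    move_to_freeze_cs: 0.10
    freeze_to_move_cs: 0.02
    move_to_freeze_out: 0.02
    freeze_to_move_out: 0.10
    min_bout: 1
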