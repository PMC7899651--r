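# perifreeze file formats

All tables are plain CSV with a header row; times are seconds from session
start, written with a decimal point. Intervals are half-open `[start, end)`.

## Spikes CSV (`spikes.csv`)

| column    | type   | meaning                                   |
|-----------|--------|-------------------------------------------|
| `unit_id` | string | unit identifier                           |
| `time_s`  | number | spike time, >= 0, nondecreasing per unit  |

A header-only file is an empty recording. Negative or unsorted times are
rejected with the offending line number.

## Events CSV (`timeline.csv`, freeze-event tables)

| column   | type   | meaning                                         |
|----------|--------|--------------------------------------------------|
| `label`  | string | `CS_ON`, `CS_OFF`, `US_ON`, `US_OFF` (timelines) |
| `time_s` | number | event time, >= 0                                 |

Timelines carry a YAML sidecar `<file>.protocol.yaml` holding the generating
protocol (`kind`, `baseline_dur`, `cs_dur`, `cs_count`, `us_flags`, `us_dur`,
`interval_min`, `interval_max`, `post_dur`, `us_amp_mA`, `cs_level_dB`,
`total_dur`) so that a written timeline round-trips to an equal object.

## Bouts CSV (`behavior/<unit_id>.csv`)

| column    | type   | meaning                         |
|-----------|--------|----------------------------------|
| `start_s` | number | freezing-bout start (inclusive) |
| `end_s`   | number | freezing-bout end (exclusive)   |

Bouts must be sorted and pairwise disjoint with `start_s < end_s`.

## Ground truth CSV (`truth.csv`, simulator output)

`unit_id, group, baseline_rate_hz, label, multiplier` — one row per
modulation carried by a unit (`label` is `none` with multiplier 1 for
unmodulated units).

## Freezing summary CSV (`freezing.csv`)

`unit_id, group, epoch, n_obs, n_frozen, percent` — epochs are `baseline`,
`CS1..CSn`, and `CS_all` (all CS periods pooled). `percent` is empty when an
epoch is shorter than one sampling interval.

## Classification CSV (`classification.csv`)

`unit_id, event_label, n_events, responsive, direction, supra_bins, peak_z,
peak_latency_s, excluded, reason` — one row per unit per alignment
(`CS_ON`, `FREEZE_ON`, `FREEZE_OFF`). `supra_bins` is a comma-separated list
of 1-based response-bin indices. Excluded rows (no analyzable events, or a
degenerate zero-SD baseline) carry the reason.

## Z-profile CSV (`zprofiles.csv`)

`unit_id, event_label, bin_left_s, z` — one row per bin of each unit's
trial-averaged baseline-normalised profile.

## Group summary / comparisons CSV (`summary.csv`, `comparisons.csv`)

`summary.csv`: `group, event_label, n_responsive, n_total, percent`.
`comparisons.csv`: `group_a, group_b, event_label, a, b, c, d, p_two_sided`
where `(a, b)` are responsive/non-responsive counts for group_a and
`(c, d)` for group_b; `p_two_sided` is the probability-ordering two-sided
exact p-value.

## Pipeline config (YAML)

See `inst/extdata/demo_config.yaml`. Top-level keys: `seed`, `protocol`
(`kind`, optional `baseline_dur`, `cs_dur`, `post_dur`), `classifier`
(`bin_width`, `response_window`, `n_baseline_bins`, `z_threshold`,
`min_supra_bins`, `sd_denominator`), `simulation` (`groups` list,
`behavior` rates), `sampling` (`sample_interval`). Unknown keys are
rejected.

## Run manifest (`manifest.json`)

`config_md5`, `seed`, `package_version`, and the per-stage output file
lists. Stage seeds are derived from the master seed as
`(seed * 48271 + index * 9973) mod (2^31 - 1)` (see `deriveSeed()`), so any
stage re-runs bit-identically.
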