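---
title: "Peri-event analysis of single units in fear conditioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peri-event analysis of single units in fear conditioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In Pavlovian fear conditioning a mouse learns that a tone (the conditioned
stimulus, CS) predicts a footshock (the unconditioned stimulus, US); during
later retrieval, the CS alone evokes freezing, and single units in medial
prefrontal cortex show phasic activity locked to CS onset and to transitions
between freezing and movement. `perifreeze` implements the analysis path
from the session's stimulus schedule and the animal's freezing bouts to
per-unit responsiveness calls (CS-ON, Freeze-ON, Freeze-OFF) and group-level
proportion statistics, together with a synthetic-data generator that makes
every stage verifiable against ground truth.

## Session protocols and timelines

A `SessionProtocol` holds the schedule parameters; `defaultProtocol()`
supplies the standard values: a 180 s baseline; a 30 s, 75 dB white-noise
CS; a 2 s, 0.6 mA US co-terminating with reinforced trials (so
`US_OFF == CS_OFF` and `US_ON = CS_OFF − 2 s`); a 120 s post period after
conditioning and 20 s after retrieval. The fully reinforced protocol (FRF)
presents 3 CS, all reinforced, with 60–90 s between trials; the partially
reinforced protocol (PRF) presents 6 CS of which trials 1, 2 and 5 are
reinforced, with 15–60 s between trials; retrieval presents 6 unreinforced
CS with 20–60 s intervals. PRF and FRF therefore deliver the same number
(3) of CS–US pairings — a structural property the test suite asserts over
1,000 seeded timelines.

Two choices here were genuinely open:

- **Interval distribution.** The protocols state only a variable interval
  within a range. We draw inter-trial intervals (CS offset to next CS
  onset) uniform-continuous on the stated range, the simplest seedable
  choice that respects it.
- **Interval scope in PRF.** Whether the 15–60 s range applies between all
  six consecutive trials or only around the interleaved unreinforced trials
  is ambiguous; we apply it uniformly between consecutive trials.

All times are real-valued seconds with session start at 0, and every
interval in the package is half-open `[on, off)`, which makes event and bin
assignment unambiguous. `validateTimeline()` checks the structural
invariants and names the violated invariant and offending index, so
timelines read from files get the same scrutiny as built ones.

## Freezing: scoring and events

Freezing (no visible movement except breathing) enters as bout intervals.
`scoreFreezing()` emulates manual scoring every 5 s: within each epoch
(pre-CS baseline, each CS, all CS pooled) the instantaneous state is
sampled at `epoch_start + k · 5 s`, `k = 1..floor(dur/5)`, and converted to
`100 × frozen/total`. Sampling at the *end* of each interval avoids
counting the epoch-start instant twice across adjacent epochs; the
convention is configurable. An epoch shorter than one interval yields zero
observations and a missing (not 0%) percentage. Note one boundary
consequence of the half-open convention: a bout `[0, 90)` leaves the
`t = 90 s` sample in the moving state.

`extractFreezeEvents()` defines freezing onset as a bout start and
cessation as a bout end. Events with less than `preWindow = 2 s` of session
before them cannot support the shifted baseline and are excluded and
logged; exclusions never alter remaining event times. By default no minimum
separation between events is imposed and events inside CS periods are
retained (both configurable); no minimum bout duration is imposed.

## The responsiveness rule

For each unit and alignment, spikes are counted in 100 ms bins around every
event, averaged across events into a single per-bin mean count
\(\bar{x}_b\) (equal weight per event), and z-normalised against the 1 s,
10-bin baseline window:

\[ z_b = \frac{\bar{x}_b - \mu_{\mathrm{base}}}{\sigma_{\mathrm{base}}} \]

For CS alignment the baseline is the 10 bins immediately before CS onset;
for freeze onset/cessation it is shifted to −2…−1 s so that the baseline
and the event are temporally separate (the intervening −1…0 s bins are
computed but belong to neither window). A unit is responsive when at least
2 bins in the 500 ms response window have `z > 1.96` (excited) or at least
2 have `z < −1.96` (inhibited), with strict inequalities. Direction is
stored alongside the call: the observed firing decrease at freezing onset
appears as Freeze-ON/inhibited rather than a separate label.

Numerical and edge-case choices:

- **σ denominator** is n−1 over the 10 baseline bins (switchable to n).
- **σ = 0** (e.g. a silent baseline, or a perfectly flat profile) marks the
  profile *degenerate*: the unit is excluded from that alignment and
  logged, rather than assigned infinite z. A corollary is that "all bins
  identical" is degenerate, not z = 0.
- **"Same sign"** is read literally: positive and negative crossings are
  counted separately; two crossings of opposite sign never jointly qualify.
  In the rare case where both directions reach 2 qualifying bins, the
  direction with more bins wins, ties broken by the larger peak |z|.
- **Coverage**: an event whose full baseline+response window does not fit
  in the recording is dropped per event (and logged), not per unit.
- **Bin assignment**: bins are left-closed; a spike exactly at the event
  time belongs to the first response bin. (At 100 ms widths an exact
  interior-edge spike time is not representable in binary floating point;
  the convention is exercised in tests with binary-exact 250 ms bins.)
- `peakResponseBin()` reports the response bin with the largest |z| (ties
  to the earliest bin) with latency in seconds. Reported peak latencies for
  this rule necessarily fall within 0–0.5 s; published descriptions
  sometimes quote peak times in a unit that reads as hundreds of seconds,
  which is dimensionally inconsistent with a 500 ms window and almost
  certainly means milliseconds — the package takes no position and reports
  seconds.

## Group statistics

`fisherExact2x2()` is authored from first principles: the hypergeometric
pmf over the table's support is computed in log space via `lchoose`, and
the two-sided p-value is the probability-ordering sum — all tables with the
same margins whose probability does not exceed the observed table's
(relative tolerance 1e−12 guards floating-point ties). Two-sided exact
p-values are convention-dependent; probability ordering is the convention
of mainstream implementations, and the suite checks exact agreement with an
exhaustive enumeration oracle over all tables with both margins ≤ 20 (and
with `fisher.test`). No multiplicity correction is applied across pairwise
group tests by default (raw exact p-values are reported); a correction hook
exists in `summarizeGroups()`.

`pairedT()` implements `t = mean(d)/(sd(d)/√n)`, df = n−1, two-sided p from
the t distribution; zero-variance differences are flagged degenerate with
no p. For the pooled baseline-vs-response comparison across responsive
units, whether the paired values should be mean z over baseline bins or raw
rates is not fixed by convention; `baselineVsResponse()` uses mean z over
baseline bins vs mean z over response bins as the package default, and
`pairedT()` accepts any pairing.

## The synthetic-data generator

The generator defines the study conditions the analysis is tested under; it
is deliberately simple enough to audit.

**Spikes.** `simulateSpikeTrain()` realizes an inhomogeneous Poisson
process with piecewise-constant rate: baseline rate × the product of all
active boxcar multipliers. Sampling is by thinning against the maximal
rate, which is exact for piecewise-constant rates. Effects are boxcars
(latency, duration; default 0.5 s at zero latency) rather than smooth
kernels because the analysis integrates over a fixed 500 ms window, and a
boxcar makes detection power analytically approachable. Baseline rates in
cohorts are drawn log-normal around the group mean (strictly positive and
right-skewed, like cortical rates); the default 4 Hz mean with
`sdlog = 0.5` places most units in the 1–5 Hz range reported for this
preparation. Published work gives no quantitative effect sizes for unit
modulation, so multipliers are chosen for testability (3–5× is cleanly
detectable at these baselines with 6 events), documented as such, and are
parameters, not estimates.

**Behaviour.** `simulateBehavior()` runs a two-state (move/freeze)
continuous-time Markov chain with CS-conditional transition rates. The
defaults (move→freeze 0.10/s and freeze→move 0.02/s during CS; reversed
outside) give a stationary freezing fraction of ~83% during the CS and
~17% outside — strong CS-evoked freezing with dwell times of tens of
seconds, typical of conditioned mice. Dwells shorter than `minBout = 1 s`
are merged into the surrounding state (shortest first), since sub-second
freezes would not be scored by a human observer. Freeze-modulated units
can use a multiplier < 1 at `FREEZE_ON` to emulate firing decreases at
freezing onset; direction is a parameter.

**Cohorts.** `simulateCohort()` assigns exactly `floor(fraction × n)` units
per group to each modulation (deterministic, seed-independent counts) and
retains ground-truth labels, enabling recovery tests: classified-responsive
fractions must be higher among truly modulated units, and the exact test
must flag the group difference in the large-effect regime.

**What the generator does not emulate** — refractory periods, bursting,
non-Poisson count dispersion, waveform/sorting artefacts, slow
nonstationarity, correlated units, behaviour–spike latency structure beyond
the boxcar, and context or pharmacology effects. Passing tests therefore
show the *analysis rule* behaves correctly under its stated assumptions,
not that recorded cortical data meet those assumptions.

## Calibration and power, at desk scale

Because the classifier's σ is estimated from only 10 near-Poisson baseline
bins, its null false-positive rate is not the nominal two-bin Gaussian
value and has no convenient closed form; the suite therefore compares the
full pipeline (simulated trains → binning → z → rule) on 10,000 homogeneous
4 Hz units against an independently coded brute-force Monte-Carlo oracle of
the identical rule (10^5 units drawing bin counts directly as Poissons),
requiring agreement within 3 binomial standard errors — both land near an
~7.5% two-sided rate at these settings. Detection rate is checked to be
nondecreasing across boxcar multipliers {1, 1.5, 2, 3, 5} (1,000 units per
level, fixed seeds) and ground-truth recovery is required in 20/20
replicate cohorts (50 units/group, 40% modulated at 3× vs 0%). Problem
sizes throughout the suite (events ≤ 6, units ≤ 10^4 per check, sessions
≤ 1,000 s) were chosen so the full suite runs in a couple of minutes on one
CPU while keeping Monte-Carlo bands tight enough to be meaningful.

## Reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state. Pipeline stages derive their seeds from the master seed by a
fixed documented map (`deriveSeed()`), so single stages can be re-run
bit-identically; `runAll()` outputs are byte-identical across invocations,
which the suite asserts file by file.

## Known limitations

- The classifier operates on one trial-averaged z-trace per unit;
  per-event z-scoring and event-count weighting across units are out of
  scope (events are equally weighted within a unit).
- The exact test is conditional on both margins and conservative at these
  sample sizes, as the null-calibration test documents.
- CSV is the only interchange format; proprietary acquisition formats and
  NWB are out of scope.
- Figure generation (PSTH/heat maps) is left to the user's plotting stack;
  the z-profile CSV (`zprofiles.csv`) contains everything needed, ordered
  by `peak_latency_s` if a latency-sorted heat map is wanted.
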