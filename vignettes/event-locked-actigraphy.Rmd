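---
title: "Event-locked actigraphy analysis of cluster-headache attacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked actigraphy analysis of cluster-headache attacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Cluster-headache (CH) attacks are short (15–180 min), extremely painful,
and classically described with restlessness and agitation — yet clinical
lore also reports patients who sit still under an oxygen mask. Wrist-worn
accelerometry offers an objective way to ask what actually happens to
movement, and movement-related energy expenditure, around an attack.
`actidelta` implements that analysis end to end for raw tri-axial
acceleration sampled on a uniform grid (32 Hz, ±2 g by default, the
Empatica E4 accelerometer configuration), paired with a patient-kept
attack diary of onsets, ends, pain intensity and acute treatments.

## The activity index

The core statistic is the absolute activity index. For a window of fixed
length $H$ (1 s, i.e. 32 samples at 32 Hz), with $\sigma_m^2$ the signal
variance of axis $m \in \{x, y, z\}$ over the window and $\sigma_i^2$ a
systematic device-noise variance,

$$\mathrm{AI} = \sqrt{\max\!\left(0,\; \tfrac{1}{3}\sum_{m}\left(\sigma_m^2 - \sigma_i^2\right)\right)}.$$

For the device modelled here the systematic noise is negligible, so
$\sigma_i = 0$ by default and the zero floor is inert (it is kept so the
general form stays correct when $\sigma_i > 0$ is configured). Windows
tile the recording without overlap, clock-aligned; per-second values are
averaged within each minute. Because the AI is a variance statistic it is
invariant to the gravity component and to sensor orientation, homogeneous
of degree one in amplitude, and symmetric across axes — all enforced by
tests.

Within an interval of interest, the per-minute AI values form a markedly
non-normal distribution, so intervals are summarized by quantile features:
the 25th, 50th, 75th and 90th percentiles (linear interpolation between
order statistics, `stats::quantile` type 7). The 90th percentile targets
high-intensity movement.

Defaults that matter:

| parameter | default | meaning |
|---|---|---|
| `window_seconds` | 1 s | variance window $H$ |
| `sigma_i` | 0 g | systematic noise SD |
| `variance_estimator` | `sample_n_minus_1` | unbiased sample variance; the $n$ divisor is available and every oracle test recomputes under the configured choice |
| `min_valid_fraction_per_window` | 1.0 | a 1-s window must be fully valid |
| `min_valid_seconds_per_minute` | 30 | a minute must have half its seconds |

The window and minute completeness floors are choices of this package:
requiring a full window keeps the variance estimator's denominator fixed,
and the 30-second floor mirrors the 50%-complete convention common in
actigraphy epoching. Both are configurable and recorded in the run log.

## Off-body exclusion

Recordings contain stretches where the device measures while not worn
(charging, showering). These show near-zero variance on all three axes
with a frozen gravity orientation. Detection is a variance floor: 5-min
windows with per-axis SD below 0.004 g on all axes become candidates;
candidate run edges are refined outward in 1-min steps while still quiet
(without refinement a coarse 5-min tiling misclassifies up to 10 min at
each edge); runs shorter than 15 min are discarded; surviving runs closer
than 2 min are merged. Quiet wear — sleep — stays above the floor because
postural micro-adjustments and orientation drift keep the 5-min SD near
0.01 g. Blocks that are mostly missing yield no wear decision: gaps are
not evidence of non-wear. Off-body exclusion runs before data ratios and
AI computation, so an off-body interval counts as missing data everywhere
downstream.

## Eligibility and matched comparison intervals

An attack enters the analysis if

1. **daytime**: its `[onset, end)` interval does not intersect any nightly
   23:00–07:30 window (wall-clock, timezone-aware);
2. **data ratio**: at least 75% of its grid samples are present and
   on-body (boundary inclusive — exactly 25% missing still passes);
3. **a matched comparison exists** (below).

Matched non-attack candidates are the same wall-clock range on every other
day of the study with the same day-type (weekday vs weekend), kept only
when at least 24 h from the start and end of *every* attack
(boundary-inclusive, measured from any point of the candidate window),
not on a configured holiday (holidays break routine activity; a helper
supplies the Belgian set), and themselves at the 75% data ratio. All
qualifying candidates are pooled into a single comparison distribution —
more candidate minutes mean a more stable baseline. Attacks on holidays
are retained; the holiday rule filters comparison days only, since the
attack itself is the object of study. A window crossing midnight inherits
its start date's day-type.

Per attack and percentile $q$, the delta is

$$\Delta_q = \mathrm{CH}_q - \mathrm{nonCH}_q,$$

so negative values mean less movement during the attack. (The sign
convention is chosen so that reduced attack-time activity reads as a
negative delta; the swapped convention is its exact mirror.)

## Inference

Across eligible attacks, each percentile's deltas are tested with a paired
two-tailed Wilcoxon signed-rank test: exact p-values from the signed-rank
null distribution for $n \le 25$ untied differences, otherwise a normal
approximation with midranks, tie correction and continuity correction.
Zero differences are dropped by default (classic rule); Pratt's method —
zeros kept in the ranking, null moments shifted — is available by
configuration. Bonferroni correction uses an explicit family size:
$m = 4$ (one test per percentile) for the whole-attack analysis.

The onset-relative analysis repeats the construction for seven fixed bins
anchored at onset — $[-3h,-1h)$, $[-1h,-30m)$, $[-30m,0)$, $[0,+30m)$,
$[+30m,+1h)$, $[+1h,+2h)$, $[+2h,+3h)$ — each matched on its own clock
range and kept only when both sides reach the 75% ratio. By default a bin
overlapping nighttime is dropped (strict mode); the lenient alternative,
keeping such bins subject only to the ratio rule, is a configuration
switch, since either reading is compatible with a daytime-only attack set.
Here $m$ defaults to the number of (bin × percentile) tests actually
performed, and per-bin sample sizes are reported because they genuinely
vary.

## The synthetic-study generator

No public recording of this kind exists, so the generator is a first-class
module: every operating characteristic claimed for the pipeline is
measured on studies it produces.

Latent activity is a minute-resolution semi-Markov chain over four states
— rest, low, moderate, high — with acceleration noise SDs 0.005, 0.03,
0.10, 0.30 g and mean bout dwells 20, 5, 3, 1 min. Hourly profiles give
the *time occupancy* of each state (night hours 88% rest; waking hours
15/35/30/20%); bout-draw weights are occupancy divided by mean dwell so
occupancy comes out as specified. Each bout carries a lognormal intensity
multiplier (sdlog 0.35), which makes the per-minute AI distribution
continuous rather than a four-atom mixture. Emitted samples are a slowly
drifting unit gravity vector (random-walk orientation, 0.02 g per-minute
step) plus state noise; the AI is location-invariant, so gravity does not
bias the statistic, but its drift is what keeps quiet wear above the
off-body variance floor.

Attacks are drawn with durations from a Gaussian (mean 37, SD 25 min)
truncated to the 15–180 min CH range, and are placed on a small set of
"bout days" — cluster-headache attacks arrive in bouts, often several per
day — which also leaves attack-free days available as matched comparison
days. An attack multiplies the high-state occupancy by `attack_effect`
from 30 min before onset (configurable) to attack end; the displaced
occupancy is exchanged with rest, on the reasoning that a patient holding
still during an attack is resting, not redistributing movement across
intensities. `attack_effect = 1` leaves the generative process literally
untouched (the identical random stream is consumed), so null studies are
exact. Off-body segments freeze the gravity orientation with 0.001 g
noise; streaming gaps arrive as geometric bursts (mean 2 s) alternating
with geometric valid runs sized to the target loss fraction. A single seed
drives everything; identical configurations are byte-identical.

What the generator does *not* emulate: real tremor and gait spectra
(noise is white within a state), registration errors in the diary
(onsets are exact), postural sleep structure, device temperature or EDA
channels, and any coupling between pain intensity and movement beyond the
single effect multiplier. Passing tests therefore demonstrate that the
pipeline's logic and inference behave correctly under the assumed data
structure, not that the biological effect exists — that question needs
patients, not simulations.

## Operating characteristics measured in the test suite

Two simulation studies are part of the acceptance tests (the acceptance
script reruns them with somewhat fewer replicates), at sizes chosen to
keep a full run in minutes:

* **Null calibration.** 7-day studies at 8 Hz with 15 attacks on three
  weekday bout days and `attack_effect = 1`, 200 replicates: the
  family-wise rejection rate of the whole-attack analysis at
  Bonferroni-corrected α = 0.05 must lie in the binomial band
  [0.01, 0.09]. Off-body detection is skipped in these runs — no off-body
  periods are injected, and the stage has its own recovery tests.
* **Effect recovery.** 14-day studies at 8 Hz, 15 attacks,
  `attack_effect = 0.2` from 30 min pre-onset, 50 replicates: median
  $\Delta_{p75}$ and $\Delta_{p90}$ negative in ≥95% of runs, adjusted
  p90 p < .05 in ≥80%, and the two most negative onset-relative bins
  (by median $\Delta_{p90}$ across runs) must be $[-30m, 0)$ and
  $[0, +30m)$ — exactly where the injected effect is fully active. The
  14-day length matches the default 21-day design more closely and gives
  each attack several pooled comparison days, as in a real study.

One methodological caveat surfaced while building the null tests: per-
minute AI values are serially dependent through the bout structure, so a
two-sample test that treats minutes as iid draws (e.g. Kolmogorov–
Smirnov on attack minutes vs matched minutes) rejects far above nominal
even when the generating processes are identical. The exchangeable unit
is the per-attack delta, which is what the pipeline's Wilcoxon consumes;
the generator's own null test works at that level.

## Numerical and degenerate-input choices

* Variance windows are centered before squaring; against a ~1 g gravity
  offset the one-pass sum-of-squares form loses low-variance windows to
  cancellation. The vectorized path must match a naive per-window loop to
  1e-12 (tested).
* Quantiles: type-7 linear interpolation; a different rule can be passed
  through but every derived expectation in the tests is recomputed via an
  explicit sort-and-interpolate oracle.
* A single attack still produces its delta row; the signed-rank test on
  one pair returns p = 1. All-zero deltas return p = 1 with a warning.
* An empty eligible set produces an empty report with an explanation and
  a complete ledger, not an error; every attack receives exactly one
  terminal status (nighttime / low data ratio / no match / eligible).
* Intervals are half-open `[start, end)` everywhere; event timestamps are
  minute-precision; recordings must start on a whole second (whole minute
  for minute-level analyses).
* E4-dialect counts are integers at 64 counts/g; writing rounds to the
  nearest count, so the dialect round-trips exactly for count-quantized
  data. The generic CSV dialect round-trips to better than 1e-9 g.

## Limitations

Single-participant scope per run (matching is within-person by design;
batching over participants is a loop). The daytime rule uses one fixed
nighttime window rather than per-person sleep staging. The wear detector
uses the accelerometer only; multi-channel detectors (temperature, EDA)
are out of scope. Holiday handling assumes the Belgian calendar unless
configured otherwise. And the simulation studies above are statements
about this pipeline under this generator — encouraging, but not clinical
evidence.
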