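# actidelta

Event-locked analysis of wrist-worn actigraphy around cluster-headache
(CH) attacks. Given a raw tri-axial accelerometer stream (32 Hz, ±2 g —
the Empatica E4 configuration — or any uniform-grid recording) and a
patient-kept attack diary, `actidelta` answers: *does movement-related
energy expenditure change during and around attacks, compared with
matched attack-free time?*

The pipeline:

1. **Activity index.** Per 1-s window of 32 samples, with per-axis signal
   variance σ²ₘ and systematic noise variance σ²ᵢ (0 for this device),

   AI = √( max(0, ⅓ Σₘ (σ²ₘ − σ²ᵢ)) ),  m ∈ {x, y, z},

   averaged into per-minute values. Interval distributions are summarized
   by their 25th/50th/75th/90th percentiles.
2. **Off-body exclusion.** Variance-floor detection (per-axis SD
   < 0.004 g over 5-min windows, 1-min edge refinement, 15-min minimum
   run) removes worn-off periods before anything else is computed.
3. **Eligibility.** Attacks must be daytime (no overlap with 23:00–07:30)
   and ≥75% complete; comparison intervals are the same wall-clock range
   on other same-day-type, non-holiday days, ≥24 h from every attack, and
   are pooled per attack.
4. **Inference.** Per-percentile deltas Δq = CHq − nonCHq (negative =
   less movement during the attack) are tested across attacks with exact
   paired Wilcoxon signed-rank tests under Bonferroni correction — for
   whole attack intervals and for seven onset-relative bins from −3 h to
   +3 h.

Because the motivating data are private patient recordings, the package
ships a synthetic-study generator (semi-Markov activity states, diurnal
occupancy, embedded attack effects, streaming gaps, off-body segments)
that reproduces the data structure, so every stage — and the pipeline's
null calibration and power — is testable end to end.

## Worked example

Simulate a two-week study with nine attacks in three day-clusters, a
strong movement suppression (high-intensity activity reduced to 20% from
30 min before onset to attack end), then run the full analysis:

```r
library(actidelta)

cfg <- synth_config(study_days = 14, sample_rate_hz = 8, n_attacks = 9,
                    attack_days = c(2, 3, 9), attack_effect = 0.2, seed = 11)
sim <- generate_recording(cfg)
run <- run_pipeline(sim$recording, sim$events, run_config())
print(run)
#> <actidelta_run>
#>   funnel: total=9 -> daytime=9 -> data_ok=9 -> eligible=9
#>   whole-attack tests:
#>      analysis bin_id percentile n statistic      p_raw m    p_adj
#>  whole_attack  whole        p25 9        20 0.82031250 4 1.000000
#>  whole_attack  whole        p50 9        16 0.49609375 4 1.000000
#>  whole_attack  whole        p75 9         6 0.05468750 4 0.218750
#>  whole_attack  whole        p90 9         0 0.00390625 4 0.015625
```

All nine attacks pass the daytime, data-ratio and matching rules (the
funnel line), and the injected suppression shows up where it should: the
90th-percentile test is significant after Bonferroni correction
(p_adj = 0.016; the statistic 0 means every attack's Δp90 was negative),
while the 25th and 50th percentiles — which the high-intensity effect
barely touches — stay null. The onset-relative analysis localizes the
effect around onset:

```r
sr <- run$onset_relative$stat_report
sr[sr$percentile == "p90", ]
#>        analysis    bin_id percentile n statistic      p_raw  m    p_adj
#>  onset_relative  -3h..-1h        p90 7         1 0.03125000 28 0.875000
#>  onset_relative -1h..-30m        p90 9         7 0.07421875 28 1.000000
#>  onset_relative   -30m..0        p90 9         0 0.00390625 28 0.109375
#>  onset_relative   0..+30m        p90 9         0 0.00390625 28 0.109375
#>  onset_relative +30m..+1h        p90 9        10 0.16406250 28 1.000000
#>  onset_relative  +1h..+2h        p90 9         2 0.01171875 28 0.328125
#>  onset_relative  +2h..+3h        p90 9         9 0.12890625 28 1.000000
```

The smallest raw p-values sit in the [−30 min, 0) and [0, +30 min) bins —
exactly the span where the injected effect is fully active (n varies per
bin because every bin must pass the 75% data-ratio rule on both the
attack and the matched side; the family here is all 28 bin × percentile
tests, so nothing survives correction at this small n — mirroring how
short per-bin samples behave).

`write_report_bundle(run, "out/")` writes the eligibility ledger, delta
tables, statistics and a run log as CSV/JSON. A thin command-line front
end lives at `inst/cli/actidelta.R` (`simulate` / `analyze`).

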