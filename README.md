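# electromeR

Approximate-entropy analysis of fruit electrome recordings.

Plant tissues carry continuous low-voltage electrical activity — the
*electrome* — measurable as micro-volt (µV) potential differences between
electrodes inserted near the vascular bundles. In ripening tomato fruit the
*regularity* of that signal changes with ripening stage: recordings become
markedly more regular (lower complexity) when a fruit enters the breaker
stage, and partially recover toward light red. `electromeR` is a toolkit for
researchers in plant electrophysiology who want to quantify and test that
kind of pattern:

- an exact, verified **approximate entropy** implementation,
  `ApEn(m, r) = φ^m(r) − φ^(m+1)(r)`, with the standard biosignal defaults
  `m = 2` and `r = 0.2 × SD`, natural log, Chebyshev (max-norm) or Euclidean
  match metric, inclusive match rule, self-matches included (fast compiled
  kernel plus a pure-R brute-force oracle for verification);
- readers/writers for uniformly sampled voltage time series (CSV/TSV with
  `time_s, voltage_uV` columns; 62.5 Hz default rate), stage schedules, and
  windowed ApEn profiles, plus light preprocessing (drift removal,
  decimation);
- a seeded **synthetic cohort generator** built on the MIX(p) regularity
  benchmark (sinusoid/uniform-noise blend), producing multi-day, per-fruit
  labeled recordings whose regularity varies by stage;
- **ripening analysis**: sliding-window ApEn profiles, per-stage summaries,
  running-median-smoothed detection of the breaker-stage entropy dip, and
  stage-transition timing summaries;
- a deterministic **nearest-centroid stage classifier** over six windowed
  features (ApEn, SD, skewness, excess kurtosis, mean absolute successive
  difference, lag-1 autocorrelation);
- a CLI (`inst/scripts/electrome`) with `simulate`, `apen`, `profile`,
  `analyze` and `classify` subcommands, writing replayable JSON manifests.

The statistic: for a series `x_1..x_N`, form the `N − m + 1` template vectors
of `m` consecutive samples; `C_i^m(r)` is the fraction of templates within
distance `r` of template `i`, and `φ^m(r)` is the mean of `ln C_i^m(r)`.
Low ApEn means repetitive, predictable dynamics; high ApEn means irregular
ones. The tolerance `r` is taken as a fraction (default 0.2) of the
population SD of the series being analyzed, so windowed profiling adapts `r`
per window.

## Worked example

Simulate a small cohort (4 fruits, desk-scale 120 s acquisitions per
simulated day), profile each fruit's multi-day recording with 512-sample
windows, and summarize ApEn by ripening stage:

```r
library(electromeR)

co    <- simulate_cohort(cohort_config(n_fruits = 4, seconds_per_day = 120,
                                       master_seed = 42))
profs <- profile_cohort(co, window_len_samples = 512)
stage_summary(profs, co$trajectories)
#>   stage mean_apen    sd_apen n_windows n_fruits
#> 1    MG 1.4693793 0.03002234       210        4
#> 2     B 0.9387015 0.05723498       140        4
#> 3    LR 1.4107677 0.03497441       154        4
```

Mean windowed ApEn drops from ~1.47 nats at mature green (MG) to ~0.94 at
breaker (B) and recovers to ~1.41 at light red (LR) — the dip-and-recovery
pattern the pipeline is built to detect. Per fruit, the dip detector locates
the entropy minimum and the stage containing it:

```r
detect_dip(profs[["fruit01"]], trajectory = co$trajectories[["fruit01"]])
#> <dip_report> fruit01: dip at window 96 (t = 518490..518498 s), ApEn 0.8839, stage B
#>   pre-dip median 1.4575, post-dip median 1.4130
```

Stage-transition timing across the cohort:

```r
transition_days_summary(co$trajectories)
#>   from_stage to_stage mean_days   sd_days n_fruits
#> 1         MG        B      3.75 0.4330127        4
#> 2          B       LR      2.50 0.5000000        4
```

Single-series ApEn with the package defaults:

```r
apen(mix_process(1000, 0.2, seed = 1))
#> ApEn(m = 2, r = 0.2 x SD) = 1.047017 nats  [N = 1000, r = 0.200594]
```

Every ApEn value can be cross-checked against the independent brute-force
implementation: `apen_oracle()` agrees with `apen()` to within 1e-10.

## Command-line interface

```sh
inst/scripts/electrome simulate --seed 7 --out cohort/
inst/scripts/electrome apen --input cohort/fruit01_day001.csv
inst/scripts/electrome profile --input cohort/fruit01_day001.csv \
    --window 2048 --out fruit01_day001.tsv
inst/scripts/electrome analyze --profiles profiles/ \
    --schedules cohort/schedules.csv --out analysis/
```

Directory-writing subcommands record a `manifest.json`;
`replay_manifest()` re-executes a run byte-identically from it.

See `vignettes/electrome-complexity.Rmd` for the model, parameter choices,
what the synthetic generator does and does not emulate, and known
limitations.
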