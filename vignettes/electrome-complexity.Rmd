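---
title: "Quantifying fruit electrome complexity with approximate entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fruit electrome complexity with approximate entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(electromeR)
```

## The problem

Surface electrodes on fruit tissue record a continuous micro-voltage signal
— the electrome — that superimposes many bioelectrical processes (ion fluxes,
action- and variation-potential-like transients, slow metabolic drifts).
In climacteric fruit such as tomato, ripening reorganizes this activity:
recordings become distinctly more *regular* when a fruit enters the breaker
stage and partially recover their irregularity toward light red. `electromeR`
implements the regularity statistic used to expose that pattern, approximate
entropy, together with the windowing, summarization and classification steps
needed to analyze multi-day per-fruit recordings, and a synthetic cohort
generator so the full pipeline is testable without laboratory data.

## Approximate entropy

For a uniformly sampled series $\Delta V = \{x_1, \dots, x_N\}$ and embedding
dimension $m$, form the $N - m + 1$ overlapping template vectors
$v_i = (x_i, \dots, x_{i+m-1})$. With tolerance $r$,

$$C_i^m(r) = \frac{\#\{j : d(v_i, v_j) \le r\}}{N - m + 1}, \qquad
\varphi^m(r) = \frac{1}{N-m+1} \sum_i \ln C_i^m(r),$$

$$\mathrm{ApEn}(m, r) = \varphi^m(r) - \varphi^{m+1}(r).$$

Low values indicate repetitive, predictable dynamics; high values indicate
irregular ones. The implementation makes the following choices explicit:

- **Defaults** $m = 2$, $r = 0.2 \times \mathrm{SD}$: the standard choice for
  biosignal regularity analysis, and the convention this package's fruit
  pipeline assumes throughout.
- **Tolerance scoping.** $r$ is computed once from the population
  (divide-by-$N$) SD of *the exact series passed in*. A windowed caller
  therefore gets a per-window tolerance, which keeps ApEn invariant to
  amplitude differences between windows; `windowed_apen(r_absolute =)`
  provides a global-tolerance override for sensitivity analyses.
- **Match metric.** Chebyshev (max-norm) is the default, following the
  classical formulation of the statistic; Euclidean distance is a first-class
  option because parts of the applied literature describe the match rule in
  Euclidean terms. Which norm a given study used is often not recoverable
  from its text, so both are implemented and tested; for $m = 2$ they rarely
  disagree by much, but they are not identical.
- **Inclusive matching.** A pair at distance exactly $r$ counts as a match.
  Both engines compare squared Euclidean sums against $r^2$ (never through a
  square root), so boundary pairs behave identically in the fast and the
  reference path.
- **Self-matches included** (default): every $C_i \ge 1/(N-m+1)$, all
  logarithms are finite, and $\mathrm{ApEn} \ge 0$. With
  `self_match = FALSE`, an unmatched template is a hard error naming the
  template, never a silent `-Inf`.
- **Natural logarithm** throughout; values are in nats.
- **Degenerate input.** A constant series has SD 0, hence $r = 0$; identical
  vectors still match at distance 0, every $C_i = 1$, and ApEn is exactly 0.
  This is a defined result, not an error.
- **Length guards.** Hard error below $N = m + 3$ (both $\varphi$ terms need
  at least two templates); a warning below $N = 50$, where the estimator's
  bias is substantial. Non-finite samples are rejected rather than dropped,
  because silently skipping gaps would change embedding adjacency.

`apen()` runs a compiled $O(N^2)$ kernel; `apen_oracle()` is an independent
plain-R transcription of the definition, guarded to $N \le 2000$, kept free
of shared code so the two can be compared as genuinely separate routes. The
test suite asserts agreement within $10^{-10}$ across hundreds of seeded
series under both metrics, exact zero on constants, affine invariance
(ApEn$(a x + b)$ = ApEn$(x)$ when $r$ tracks the SD), and the regularity
ordering periodic < noise.

## Signal I/O and preprocessing

Series files are delimited text with `time_s` and `voltage_uV` columns,
written at full double precision so a write/read round trip is lossless. The
sampling rate is re-derived from the median time step on read and checked
for uniformity (relative jitter at most $10^{-6}$); non-monotone time,
missing columns and non-finite values are distinct, named errors. The
default rate is 62.5 Hz, the acquisition convention this pipeline assumes.

`preprocess_series()` offers two optional steps, applied in order:

1. **Detrending**: subtraction of a centered moving mean. Near the edges the
   half-width shrinks symmetrically, which keeps the window centered on each
   sample and removes a purely linear trend *exactly*; this is a software
   analogue of the high-pass conditioning used in acquisition hardware.
2. **Decimation**: keep-every-$k$th with `fs` updated to `fs / k`; refused if
   fewer than 64 samples would remain.

A hardware-style low-pass at kilohertz cutoffs would sit far above the
31.25 Hz Nyquist frequency of a 62.5 Hz recording and is therefore a no-op
for stored data; it is documented rather than simulated.

## The synthetic cohort generator

The generator emulates the *statistical* structure the analysis assumes,
not fruit biophysics. Its core is the MIX$(p)$ regularity benchmark:
$x_j = \sqrt{2}\sin(2\pi j/12)$ with each sample independently replaced, with
probability $p$, by a $\mathrm{Uniform}(-\sqrt{3}, \sqrt{3})$ draw. Both
components have unit variance, so $p$ tunes regularity while leaving the
variance — and hence the ApEn tolerance and the SD feature — essentially
unchanged. Expected ApEn increases monotonically in $p$.

A fruit-day acquisition is
`amplitude_uV * MIX(mix_p) + drift + spikes`: a linear baseline drift
(µV/hour) plus Poisson-timed biphasic spikes (one sample up by
`spike_amplitude_uV`, the next down) standing in for transient
depolarization-like events. Defaults, chosen once:

| parameter | default | rationale |
|---|---|---|
| `mix_p` MG / B / LR | 0.6 / 0.2 / 0.5 | reproduces the qualitative ripening pattern: irregular at mature green, a pronounced regularity dip at breaker, partial recovery at light red; only the orderings MG > B and LR > B are treated as ground truth |
| stage durations (days) | MG 4 ± 1, B 2 ± 0.7, LR 2 ± 0.7 | realistic for detached cherry tomato ripening at ~25 °C; truncated-positive normal, rounded to whole days with a 1-day floor |
| `amplitude_uV` | 10 | order-of-magnitude placeholder: µV-scale electrode recordings; absolute amplitude statistics of real fruit electromes are not established |
| `drift_uV_per_hour` | 2 | slow baseline wander, stage-independent |
| spikes | 2 / h at 50 µV | sparse transients, stage-independent: stage differences are carried by regularity alone, so amplitude, drift and spike settings are deliberately identical across stages |
| `n_fruits` | 20 | five repetitions of four fruits, the cohort layout this pipeline assumes |
| `seconds_per_day` | 1200 | a 20-minute stand-in for a 24 h acquisition; `86400` gives full days |
| `fs` | 62.5 Hz | acquisition convention |

Randomness is organized per (master seed, fruit, day) through a pure integer
`child_seed()` function: cohorts regenerate byte-identically from their
configuration, and fruits' streams are independent.

**What passing tests do and do not show.** The generator produces
stage-dependent regularity, per-fruit transition-time variation, µV
amplitudes, drift and sparse transients. It does *not* reproduce
nonstationarity within a stage, circadian structure, electrode artifacts,
colored noise, or any ethylene/calcium mechanism — so a pipeline that passes
on synthetic cohorts is shown to be *correct and sensitive for the assumed
signal structure*, not validated on real fruit. One known artifact of the
MIX construction: regularity changes also leave a linear signature (lag-1
autocorrelation falls as $p$ rises), so features other than ApEn also
separate stages on synthetic data; the feature-informativeness comparison
rests on ApEn's robustness to spike-contaminated windows, where the
moment-based features fail.

## Ripening analysis

- **Windowing.** Default window 2048 samples (~33 s at 62.5 Hz), step =
  window, i.e. non-overlapping: no windowing convention is canonical in the
  applied literature, and non-overlap keeps windows statistically
  independent for the stage summary. Trailing partial windows are dropped:
  `n_windows = floor((N - window) / step) + 1`.
- **Stage summary.** Each window is assigned to the stage covering its
  midpoint at day resolution; windows outside every interval are counted and
  reported (`n_unassigned`), never silently dropped. Means and SDs pool
  windows within stage across fruits and are invariant to fruit order.
- **Dip detection.** Running-median smoothing (default width 5; median
  rather than mean to resist spike-contaminated windows), then the *global*
  minimum of the smoothed profile — per-fruit ripening profiles show a single
  broad trough, so a global rule is more stable than first-local-minimum.
  Ties break toward the earliest window. Pre-/post-dip medians are reported;
  a dip at a boundary leaves the corresponding median undefined (`NA`).
- **Transition timing.** For each consecutive stage pair, the mean and
  population SD of days spent in the earlier stage, across fruits
  (population SD so that a single fruit reports SD 0, not `NA`).

## Stage classification

A nearest-centroid classifier was chosen over trained black-box models: it
is fully specifiable, deterministic and dependency-free. Features are
standardized by global median and IQR (a zero-IQR feature keeps scale 1 and
is flagged), centroids are per-stage means in standardized space, rows go to
the nearest centroid in Euclidean distance, and ties break toward the
earlier canonical stage (IMG < MG < B < OR < LR < R). Standardization makes
predictions invariant to affine rescaling of any raw feature. Train/test
splits are always *by fruit*, never by window, to avoid leakage between
adjacent windows of one recording. Models serialize to JSON.

## Problem sizes used in tests and the acceptance script

Cohort-level checks run the default signal model at desk scale: 120 s of
signal per simulated day and 512-sample analysis windows (the package
defaults stay 1200 s and 2048). At this scale one 20-fruit cohort is ~2,000
windows; the acceptance script profiles 50 cohorts (~100,000 window-ApEn
evaluations), checks per-stage orderings in every cohort, localizes ~1,000
per-fruit dips, recovers stage durations from one cohort, and pools MG/B
windows of three cohorts (~2,000 test windows) for the classifier
comparison, all in a few minutes on one CPU. Oracle agreement is asserted on
hundreds of seeded series with $N \in [50, 500]$.

## Known limitations

- Absolute ApEn levels per stage are generator artifacts; only orderings and
  dip localization are meaningful test targets.
- ApEn is biased at small $N$ and not comparable across different $N$;
  profiles should use one window length throughout (the package warns below
  $N = 50$).
- The dip detector assumes one trough per recording; multi-dip trajectories
  would report only the deepest (earliest on ties).
- The classifier is linear in standardized feature space; it is meant as a
  specifiable baseline, not a performance ceiling.
- Real-data properties not emulated by the generator (see above) are
  untested by construction.
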