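---
title: "Reconstructing hourly PM2.5 series: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing hourly PM2.5 series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmgapfill)
```

## The problem

Urban PM2.5 monitoring stations lose data: sensors fail, power drops,
maintenance interrupts logging. The resulting hourly series carry missing
runs ("gaps") from a single hour to a week or more, and downstream uses -
exceedance statistics, exposure assessment, trend analysis - need a
complete series. `pmgapfill` implements a hierarchy of gap-filling methods
for such series, a quality-control pipeline that produces the hourly series
from raw minute-level sensor records, a benchmarking harness that measures
every method on synthetic gaps with known truth, and a downstream
health-threshold assessment stage.

## The quality-control pipeline

Minute-level records pass through, in order:

1. **Spike masking** - a reading is masked if it exceeds 200 µg/m³ *and*
   is more than 3× the previous reading (present predecessor required).
2. **IQR masking** - readings strictly outside
   `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`, quartiles by linear interpolation of
   order statistics over the whole minute series (the global complement of
   the local spike rule). The strict comparison means a constant series
   yields no outliers. Both masks are computed on the raw values and
   applied as a union; the sequential alternative could differ on contrived
   inputs where one mask shifts the other's fence.
3. **Delayed-timestamp correction** - readings at `hh:mm:ss` with
   `0 < ss < 15` (strict) snap back to `hh:mm:00` unless that minute is
   occupied. This runs before grid regularization because delayed records
   sit off the minute grid; on any input where both orders are defined they
   agree.
4. **Timeline regularization** - the record set is completed to a full
   1-minute grid, absent minutes becoming missing rows.
5. **Short-gap interpolation** - missing runs *shorter than* 5 minutes
   (≤ 4) with anchors on both sides are filled linearly.
6. **Hourly aggregation** - an hour's value is the mean of its valid
   minutes when *at least* 40 are present (inclusive), otherwise missing.
7. **Secondary hourly masking** - hours above 270 µg/m³, or above
   200 µg/m³ and more than 3× the previous hour, are masked.

No stage deletes rows; outliers become missing values so that they remain
candidates for gap-filling. Boundary conventions (strict vs. inclusive)
mirror the wording of each rule and are fixed in `qc_config()`.

## The imputer hierarchy

**Baselines** (`impute_global()`, `impute_local()`,
`impute_interpolation()`, `impute_ar()`): global mean/median; local
mean/median over a 15 + gap + 15 window with a documented global fallback
when the window is empty; linear, cubic-polynomial and natural-cubic-spline
interpolation through observed anchors (the curve methods use
`min(gap length, 12)` anchors per side - "variable" context resolved so
cubic fits stay well-conditioned for long gaps); and AR(1) extrapolation
fitted by maximum likelihood on up to 100 pre-gap hours (floor 10), falling
back to the local mean if estimation fails. Baselines run on the raw scale;
they are scale-equivariant, so standardization would change nothing.

**Fixed-context supervised imputers** (`imputer_spec()`, `fit_imputer()`,
`impute_gap()`) factor along three axes:

* *Strategy*: autoregressive models predict one step and recurse,
  feeding predictions back into the rolling window; sequence-to-sequence
  models emit the whole gap in one pass, one independent regressor per
  horizon step over a shared input.
* *Directionality*: unidirectional seq2seq models see both flanks
  concatenated (32/32) in a single forward pass; bidirectional methods fit
  two single-flank models - the backward one on the globally reversed
  training series, not on reversed windows, so its training distribution
  matches its inference-time input - and fuse the two predictions with
  position-dependent weights `w_i = (L + 1 − i)/(L + 1)`. The weight
  formula is a design choice: the underlying idea is only "weight
  predictions by proximity to their context"; this linear scheme is
  symmetric, never assigns zero weight, and reduces to plain averaging for
  a singleton gap.
* *Variables*: univariate models see PM2.5 only; multivariate models add
  temperature, humidity, hour-of-day (0-23) and season (1 = winter … 4 =
  autumn), flattened time-major-then-feature.

All supervised models train and predict on a standardized scale whose
statistics come from the training split only (population SD, unit floor
for constant features); errors are reported in µg/m³ after inverse
transform. The chronological 80/20 split is never shuffled.

**Backends.** The regressor family is pluggable, and no tree-ensemble
library is available in this environment, so the package ships two
compiled ensembles of its own behind one interface: `"boost"`, gradient
boosting with squared loss over randomized regression trees (50 rounds,
learning rate 0.3, depth 6 - the analog of an XGBoost-style model and the
default for the supervised and dynamic methods), and `"forest"`, a bagged
randomized-tree ensemble (extra-trees style splits, 50 estimators,
`mtry = ⌊p/3⌋` - the random-forest-style family). Both are deterministic
under a fixed seed via a self-contained RNG. Recurrent/convolutional
backends would plug into the same interface but are outside the tested
core. A ridge backend exists for fast tests.

## The dynamic adaptive-context imputer

Fixed-context models need one fit per gap length and fail near series
edges. The dynamic model (`dynamic_config()`, `fit_dynamic()`,
`fill_all()`) handles any gap with one fitted object through four
mechanisms:

1. **Dynamic context sizing** - context per side is `min(3·L, 32)` for
   gaps `L ≤ 10` h, else 32.
2. **Position-aware padding** - left contexts are zero-padded on the far
   left, right contexts on the far right, so observed values always sit
   adjacent to the gap. Padding happens on the standardized scale, where
   zero is the training mean - an uninformative value. A side with no
   observed neighbour is legal and fully padded, which is what makes gaps
   at series boundaries and closely spaced gaps tractable.
3. **Gap metadata** - the input carries the gap length and the dynamic
   context size; in multivariate mode also the hour and season of the gap
   start and, per covariate (wind speed, wind direction, temperature,
   humidity), the covariate block across the gap itself (meteorology is
   assumed observed even when PM2.5 is missing; residual holes are
   linearly interpolated). Position-within-gap is *not* fed as a feature:
   with one regressor per output position it is encoded structurally, so a
   scalar position feature would be redundant at best.
4. **Unified multi-length training with masked outputs** - training gaps
   of lengths {5, 12, 24, 48, 72} are carved from observed stretches of
   the training split; the model has 72 outputs and each example
   contributes only to the outputs its mask covers; at prediction time the
   first `L` outputs are used.

Gaps longer than 72 h are chunked: full 72-hour chunks left to right plus
a remainder (191 → 72 + 72 + 47), each chunk's prediction becoming the
next chunk's left context. Left-to-right chaining preserves continuity at
seams and needs no future predictions; a balanced split was rejected for
determinism and simplicity. Finally, negative predictions - physically
meaningless for a concentration - are clipped to zero and counted in the
fill report.

## The benchmark harness

`run_benchmark()` injects synthetic gaps of configurable lengths into the
*test split only*, at a 5% missing fraction, with every gap at least 32
points from every other gap and from the split boundaries (so every
fixed-context method always has full context available - the generator's
`min_separation` default equals the largest context any method uses).
Filling happens on the full series (training prefix plus holed test
split), so simple imputers see whole-series statistics and fixed-context
methods can draw context across the split boundary, exactly as an
operational fill would; only the *injection* is restricted to held-out
data. Within a run all methods score on the identical gap pattern; runs differ
only in placement seed while fit seeds stay constant, isolating placement
variance. Metrics (MAE, RMSE, MAPE with a 1e-8 guard, R²) are pooled over
all gap positions of a run - pooling, rather than per-gap averaging,
stabilizes R² for short gaps - and aggregated to mean ± SD over runs.
Method-inapplicable failures (insufficient anchors or context) are
recorded through a coverage column, never as zero error. R² with zero
total variance is reported missing, never ±∞.

One protocol detail: the gap-count rule `floor(f·N/L)` applied to a
desk-scale test split yields zero gaps for long lengths (e.g.
`floor(0.05·1000/72) = 0`), so the harness guarantees at least one gap per
cell; `inject_missingness()` itself follows the floor rule exactly.

## The synthetic world

`generate_series()` emulates the qualitative structure of PM2.5 in a
continental-climate city; it does not chase any particular city's marginal
distribution. Concentrations are built as

```
pm25 = base · seasonal(t) · diurnal(t) · exp(AR1(t)) + c_w · (Ff − mean(Ff)) , clipped at 0
```

* `base` 20 µg/m³; annual cosine with amplitude 0.175 peaking mid-January,
  which yields winter means 35-40% above summer means (the documented
  seasonal contrast of the target setting);
* diurnal Gaussian bumps at 08:00 (+50%) and 19:00 (+60%), the
  morning/evening rush structure;
* log-scale AR(1) noise, φ = 0.8, innovation SD 0.3 - strong
  autocorrelation and a right-skewed (lognormal-ish) positive marginal;
* additive coupling `c_w = −2` µg/m³ per m/s to the wind-speed anomaly,
  giving the negative PM2.5-wind correlation (≈ −0.2) seen in urban data;
  coupling to the anomaly rather than the level keeps seasonal means
  interpretable;
* covariates: autocorrelated wind speed (≥ 0, mildly diurnal), wind
  direction as a wrapped random walk in degrees, continental temperature
  (seasonal + diurnal + AR noise) and humidity anti-coupled to the
  temperature anomaly.

What a green test on this world establishes: the estimators, contracts and
orderings behave as designed under realistic autocorrelation, seasonality
and covariate structure. What it does not establish: performance
magnitudes on any real deposit - real sensors have regime changes,
episodic sources, simultaneous covariate dropout and non-random outage
patterns the generator deliberately omits.

## Numerical choices and degenerate inputs

* Quartiles: type-7 (linear interpolation of order statistics), recorded
  in `qc_config()`.
* Standardization uses population SD (not sample SD) and maps constant
  features to exactly 0 via a unit-SD floor.
* R² on constant observations, skewness/kurtosis of constant groups:
  missing, with a warning where the caller may be surprised.
* The paired method test returns p = 0 in the degenerate
  constant-improvement limit (t → ∞) and missing when all paired
  differences are zero.
* AQI breakpoints are configuration data (`aqi_breakpoints()`), defaulting
  to the US EPA PM2.5 table (pre-2024 revision), with concentrations
  truncated to 0.1 µg/m³ before piecewise-linear lookup - the table
  reproducing the standard six category names and mapping 251.4 µg/m³ to
  index 302. Skewness/kurtosis use bias-corrected moment definitions.
* Hourly values are compared against the WHO *daily* guideline
  (15 µg/m³); this apples-to-oranges convention is standard in this
  assessment style and is flagged here deliberately.
* Indexing is 1-based with closed ranges throughout, the R idiom; all
  documented context/length quantities are index-convention-free.
* Gap placement is rejection sampling with a hard iteration cap
  (1000 × gaps); infeasible packings fail fast with the binding constraint
  named.
* Every stochastic component (generator, placement, backend) takes an
  explicit seed; sub-seeds derive from a master seed by a fixed
  multiplicative hash and stay below 2³¹.

## Known limitations

* The tree backends use randomized split thresholds for speed; relative
  orderings among method families are preserved, exact error magnitudes of
  any specific boosting/forest library are not. On a fully observed
  training split the dual-flank unidirectional seq2seq model is nearly as
  strong as the bidirectional pair - the large bidirectional margins seen
  on fragmented real data (where 76-hour complete windows are scarce) do
  not reproduce at full completeness.
* The dynamic model's effective-context metadata reports the rule's
  intended size; actual availability is communicated through padding.
* No uncertainty intervals on filled values; single-station only (no
  spatial borrowing); meteorology is assumed near-complete across PM2.5
  gaps.
* The QC pipeline's IQR stage is global; a rolling-window variant would
  behave differently under strong regime changes.

## A worked example

```{r example, eval = FALSE}
series <- generate_series(generator_config(n_hours = 5000, seed = 1))
parts <- split_time_based(series, 0.8)

fit <- fit_dynamic(parts$train, dynamic_config(variables = "multivariate"),
                   seed = 1)
holed <- parts$test
holed$pm25[c(40:51, 300:490)] <- NA          # a 12 h and a 191 h gap
res <- fill_all(fit, holed)
res$report                                   # direct vs chunked, clip counts

summary <- exceedance_summary(res$series, "month")
```
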