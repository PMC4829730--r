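---
title: "Methods: personalized mood prediction from phone-usage logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized mood prediction from phone-usage logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`moodstep` implements, end to end, the analysis design used in
smartphone-based unobtrusive ecological momentary assessment (EMA) studies
of day-to-day mood: passive phone logs are condensed into a daily feature
vector, personalized forward stepwise regressions are trained per
participant, and their out-of-sample accuracy is compared against naive
benchmarks. This vignette documents the model, the defaults and why they
are what they are, what the synthetic generator does and does not emulate,
and the numerical decisions a re-implementer would need to know.

## Prediction targets

Participants rate mood at up to five fixed clock times per day: a
one-dimensional mood score (integer 1–10) and circumplex valence and
arousal (integers −2..2). Ratings are averaged per calendar day (day
boundaries at local midnight; a rating belongs to the day of its
timestamp). Days with no ratings are absent, never zero-filled. Daily
means are then standardized *within* each participant — z = (x − x̄)/s with
the sample SD (denominator n − 1), computed over all of that participant's
observed days. Two consequences are deliberate:

- The ±0.5 "tolerated error margin" used for the percent-correct metric is
  applied on this standardized scale for all three measures, and the
  comparison is inclusive (|error| ≤ 0.5 counts as correct).
- Standardizing on the full observed series leaks a small amount of
  held-out information (the day being predicted contributed to the mean
  and SD) into every cross-validation fold. This mirrors the common field
  practice the pipeline reproduces; selection itself is rerun inside each
  fold, so no *selection* leakage occurs. An alternative
  (training-days-only standardization) would complicate the margin's
  interpretation across folds; we kept full-series standardization and
  note it as a known bias shared by all model families equally.

A participant whose daily-mean series is constant on any measure cannot be
standardized and is dropped with a warning. Participants with fewer than
20 *complete* days — days having both a mood target and a fully computable
feature row, including the two history lags — are excluded from modeling;
a participant with exactly 20 complete days is retained.

## The 53-variable daily feature set

Thirteen feature groups expand into 53 named variables in a fixed order
(see `feature_schema()`): 15 for calls/SMS, 1 accelerometer, 2 screen, 32
app, 1 camera, 2 mood history.

**Windowed interaction histograms.** For calls (frequency and duration),
SMS (frequency) and apps (frequency and duration), the five most frequent
entities are determined once per participant over the whole study — so
"slot 3" means the same contact on every day — with ties broken by earliest
first occurrence, then lexicographic id. For each day d the event weight is
summed over the 3-day window d−2..d (the window *ends* on the predicted
day: passive data for day d are available when predicting day d's mood,
which is what a deployed system would see) and divided by the 5-slot total.
The same mechanism produces the 11-bin app-category histograms
(`built-in, communication, entertainment, finance, games, office, social,
travel, utilities, other, unknown`; unmapped apps count as `unknown`). An
all-zero window normalizes to all zeros, keeping every histogram variable
in [0, 1].

**Screen.** Daily screen-on event counts and total screen time from
matched on/off pairs, z-scored within participant across all study days.
Sessions spanning midnight are split at the boundary; a trailing
unmatched "on" closes at the next midnight; a leading unmatched "off" is
dropped; a repeated "on" extends the open session. A constant series
(zero SD) z-scores to zeros rather than NaN.

**Activity.** Phones report hourly summaries — the fraction of sampled
time with high movement — which are aggregated to a day value by a
sample-count-weighted mean; days without summaries score 0.

**Camera.** Photos per day divided by the participant's maximum daily
count (all zeros if no photos were ever taken).

**Mood history.** Lag-1 and lag-2 values of the standardized target being
predicted (same measure; the circumplex targets use their own lags). Days
missing a target or either lag are flagged non-modelable — so modeling
effectively starts on day 3. Channels with no events on a day contribute
zeros, never missingness; only targets and lags can make a row unusable.

## Model families

All families are linear and fitted per participant on the standardized
target:

- **mean**: intercept-only (predicts the training mean);
- **history**: intercept + mood_lag1 + mood_lag2 (exactly collinear lags
  fall back to the minimum-norm solution instead of failing);
- **stepAIC**: forward-only selection minimizing the Gaussian AIC
  `n log(SSE/n) + 2(k + 2)` — intercept and profiled-out variance counted
  as parameters. The additive constant `n(log 2π + 1)` is dropped; it
  cannot change any comparison between models on the same n.
- **stepCV**: forward-only selection minimizing the PRESS-based
  leave-one-out MSE `(1/n) Σ (e_i / (1 − h_ii))²`, obtained from a single
  least-squares fit via the hat-matrix diagonal.

Selection starts from the intercept-only model; each step scores every
remaining candidate and admits the best one only if it *strictly* improves
the criterion ("until the cross-validated error starts to rise"), stopping
otherwise or at the complexity cap ⌊n/5⌋ (floor division, matching 8
variables at n = 42; below 5 training points the model stays
intercept-only, applied to both stepwise variants).

Numerical decisions inside selection:

- Candidate fits use a Cholesky factorization of the Gram matrix of the
  precomputed full design, so each candidate costs O(np²) with p ≤ 9.
- A candidate whose design is numerically singular, or that produces a
  leverage ≥ 1 − 10⁻⁸ (its own fitted value would be self-determined and
  the held-out residual unbounded), is skipped — not fatal.
- Criterion ties within 10⁻¹² are broken by schema order, making selection
  fully deterministic.

## Evaluation

**Full-data LOOCV.** For each modelable day of each participant, the
entire procedure — including variable selection for the stepwise
families — is retrained on all other modelable days and predicts the
held-out day. Per participant this yields the cross-validated MSE and the
percentage of predictions within the ±0.5 margin. Participants with fewer
than four modelable rows are skipped with a warning.

**Benchmark comparisons.** Per-participant metric values of two families
are compared with a paired two-sided Wilcoxon signed-rank test: zero
differences are dropped (the Pratt alternative would be a one-line
change); up to 12 untied pairs use the exact distribution, larger or tied
samples the normal approximation with tie and continuity corrections.
All-zero differences return a degenerate result with p = 1.

**Incremental assessment.** Emulating deployment, each family is trained
on modelable days strictly before day d and predicts day d, for d from 8
(earlier forecasts were considered unfeasible; days 1–7 only ever provide
training data) to the end of the study. Metrics are aggregated per day
across participants, and the per-day difference to the mean model is
regressed on an intercept and the study day. The intercept estimates the
personalized model's handicap at the start; the slope estimates whether
accruing data closes the gap. Days without valid predictions are omitted
from the fit. Across-participant summary tables report means with normal
95% CIs (mean ± 1.96·SE; undefined and flagged NA for a single
participant).

## The synthetic generator

Real study data of this kind cannot be redistributed, so the generator is
a first-class, tested module that emulates the *statistical shape* of the
streams:

- **Event rates.** Poisson per-day counts with participant-level
  log-normal intensity multipliers (SD 0.3): defaults of 5 calls, 2 SMS,
  60 screen sessions, 100 app launches and 2 photos per day, with 24
  hourly activity summaries — chosen as plausible for student phone use
  and in line with the per-day order of magnitude implied by published
  totals of such studies. Event rates are free parameters of the study
  configuration, not calibrated quantities.
- **Concentration.** Contact and app popularity is Zipf-distributed with
  a per-participant random popularity order, so a stable "top 5" exists
  and most interactions involve few entities.
- **Missingness.** A participant-day is missing entirely with probability
  0.05 (no events, no ratings — e.g. phone off), and each individual
  prompt is skipped with probability 0.1 on observed days.
- **Mood.** A latent daily state follows
  s_d = φ·s_{d−1} + βᵀf_d + ε_d, ε_d ~ N(0, σ²), where f_d are the day's
  *standardized* behaviour features and β is the user-supplied effect
  vector (empty by default: behaviour and mood independent). Each diary
  rating maps the latent state to its scale (mood mean 7.0, SD 0.95;
  valence 0.7/0.63; arousal −0.1/1.00 — typical raw-scale moments for
  non-clinical student samples), adds N(0, 0.5) measurement noise in
  standardized units, rounds to the integer grid and clips to the scale.
  The defaults φ = 0.3 and σ = 1 give a mildly persistent, noisy mood
  series. History dependence belongs to φ; lag variables are rejected in
  the effect vector.
- **Determinism.** Participant i draws everything from child seed
  (master + i), so any participant regenerates identically regardless of
  cohort size; the caller's RNG state is saved and restored.

What the generator does *not* emulate: upload chunking and transfer
effects, contact hashing (ids are synthetic and already opaque), battery
or device heterogeneity, circadian structure within days, bursty photo
sessions, or the heavy-tailed, regime-switching character of real mood
series. The last point matters when interpreting null-data experiments:
with Gaussian latent innovations, every participant's standardized target
puts the ±0.5 margin near the steepest part of the error distribution, so
per-participant percent-correct comparisons between families are noisier
than they would be on real (leptokurtic) mood series, where long stable
stretches push the mean model's accuracy far above chance. Passing or
failing on this generator therefore speaks to the *procedures*, not to any
specific real population.

## Problem sizes

The test-suite and acceptance-script experiments use the study geometry
the design targets: 27 participants × 42 days for the cohort-level
experiments (null coupling for the benchmark-replication check; strong
two-feature coupling, σ = 0.2, for the signal-regime check), 20 replicate
single-participant studies for coupling-recovery checks, and 100+ random
small regression instances (n ≤ 30, p ≤ 6) for the PRESS/refit identity.
Determinism is verified by comparing the byte content of two complete
pipeline runs on a smaller study (3 participants × 14 days), which
exercises the identical code path at lower cost.

## Known limitations

- Full-series standardization (above) biases all families' error
  estimates slightly downward; comparisons between families are
  unaffected to first order.
- The cross-validated MSE criterion in stepCV evaluates candidates on the
  same folds it later reports, so the final "cv_mse" of a selected model
  is an optimistic estimate of generalization — which is why the outer
  LOOCV reruns the whole selection per fold.
- The app-category lookup is a static table; a real deployment would need
  an external store catalogue, which is outside the package's scope.
- Wilcoxon p-values with many tied percent-correct values rely on the
  normal approximation; at 27 participants this is standard practice but
  approximate.
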