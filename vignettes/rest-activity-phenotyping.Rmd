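---
title: "Rest-activity phenotyping and subject-level classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-activity phenotyping and subject-level classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`actirhythm` implements a complete digital-phenotyping analysis for
small clinical cohorts wearing wrist actigraphs: daily sleep and circadian
features are derived from 30-second epoch activity counts and morning sleep
logs, screened by day-level quality control, and used to classify a
person-level clinical outcome (here, PTSD status by clinician diagnosis or a
PCL-5 self-report cutoff) with gradient-boosted trees under
leave-one-subject-out cross-validation. This vignette documents the models,
the tunable parameters, the numerical choices, and what the bundled
synthetic cohort does and does not establish.

## Data model

Three tables drive everything:

* **Epoch series** — one row per 30-s epoch per participant: timestamp,
  activity count, off-wrist flag. Timestamps are local wall-clock values
  carried in a fixed UTC representation; daylight-saving transitions are
  described by explicit clock-change records rather than by the OS timezone
  database, so the quality-control rules can reason about them
  deterministically. Missing epochs are materialized as off-wrist zeros at
  read time, which keeps every day rectangular for the off-wrist rule and
  never changes the sum of observed counts.
* **Sleep logs** — one row per participant-morning: bed time, rise time,
  and two subjective ratings (sleep quality and restfulness, 1 = worst to
  10 = best). The night is keyed to the calendar date of waking.
* **Outcomes** — per participant: clinician diagnosis (0/1, possibly
  missing), PCL-5 total (0–80) with derived cutoff flags at 31 and 38, any
  current non-PTSD diagnosis (0/1), and age in years.

An analysis day is local midnight-to-midnight. The day boundary is a
genuine design choice (bed-centred days are equally defensible); we use
calendar days because the circadian features are defined on the 24-h clock
and because the waking-date convention assigns each night and its log to
exactly one day.

## Day-level quality control

A day is retained only if **all** of the following hold:

* off-wrist time below 30% of the day (`off_wrist_max = 0.30`; a day at
  exactly 30% is excluded, matching the "≥ 30%" phrasing of the rule),
* a completed sleep log exists for the waking date,
* the day is not a clock-change day nor within the following 2 days
  (`dst_exclusion_days = 2`; applied to spring and fall transitions alike),
* the day holds exactly 24 h of epochs (2880 at 30 s),
* the day is neither the first nor the last study day — those lack the
  full windows the circadian measures need, and dropping them
  unconditionally makes the design deterministic: a clean 7-day recording
  always yields days 2–6, i.e. 5 analysis days per person, and a clean
  33-person cohort yields 165 participant-days.

Retention is monotone: adding an exclusion rule can only shrink the
retained set (a property the tests assert directly).

## Night sleep metrics

Proprietary actigraphy software scores sleep with a weighted moving window
over epoch counts; we implement an open, parameterized scorer of the same
family so every number in the pipeline is reproducible. An epoch inside the
bed-to-rise interval is scored **sleep** when

\[ \sum_{j=-4}^{4} w_j \, c_{i+j} < T \]

with default weights \(w = (0.04, 0.04, 0.2, 0.2, 2, 0.2, 0.2, 0.04,
0.04)\) spanning ±2 min at 30-s epochs, zero padding at the edges, and wake
threshold \(T = 40\) (the conventional "medium" setting; 20 and 80 are the
low and high settings). Which sensitivity the source analyses used is not
recorded, so the threshold is exposed as a parameter.

Sleep onset is the start of the first run of ≥ 10 consecutive scored-sleep
minutes, offset the end of the last such run (a standard actigraphy
convention). Between onset and offset, total sleep time (TST) is the sleep
minutes and WASO the wake minutes. Efficiency uses the full bed-to-rise
interval as denominator, \(100 \cdot TST / \text{interval}\), the vendor
default. The fragmentation index is the sum of the movement index (percent
of interval epochs with any activity) and the immobility-fragmentation
index (percent of immobile bouts lasting ≤ 1 min) — the composite
"sleep fragmentation index" familiar from clinical reports; its maximum,
200, is attained by strictly alternating mobile/immobile epochs. A night
with no qualifying sleep run yields missing metrics and that day is dropped
from the feature table with a message.

## Circadian features

Each retained day contributes a single-component cosinor fit

\[ y(t) = M + A \cos\!\left(\frac{2\pi (t - t_{peak})}{24}\right), \]

estimated exactly by linear least squares on \(\cos\omega t, \sin\omega t\):
mesor \(M\), amplitude \(A \ge 0\), acrophase time \(t_{peak} \in [0, 24)\),
plus the fit's \(R^2\). A constant day has amplitude 0 and, by convention,
\(R^2 = 0\). **Circadian rhythm strength** is defined here as that cosinor
\(R^2\): the quantity has no universal definition, and variance explained
by the 24-h rhythm is the most common operationalization and is monotone in
rhythm robustness.

Nonparametric features per day: mean, SD, and RMSSD of epoch counts;
intradaily variability on hourly means,
\(IV = n \sum (x_i - x_{i-1})^2 / ((n-1)\sum(x_i - \bar x)^2)\), which is
≈ 0 for a smooth sinusoid and ≈ 2 for white noise; M10 and L5, the
extreme mean activity over all consecutive 10-h/5-h windows sliding at
epoch resolution without wrapping midnight (wrap behaviour is unspecified
in the field; not wrapping keeps the feature a property of the single day);
and relative amplitude \((M10 - L5)/(M10 + L5)\). Hourly binning for IV is
the literature standard — a single day supplies only 24 hourly values, and
epoch-level IV would be dominated by scorer noise.

Interdaily stability,
\(IS = n \sum_h (\bar x_h - \bar x)^2 / (24 \sum_i (x_i - \bar x)^2)\)
over pooled hourly means, is mathematically a multi-day quantity (1 when
the 24-h profile repeats exactly; expectation \(1/n_{days}\) for
day-independent noise). It is computed once per participant across all
retained days and broadcast to each day row, reconciling its multi-day
nature with the day-level feature table.

Off-wrist epochs are excluded from feature computations (not zero-filled)
on days that passed QC; zero-filling would bias L5 and the low end of the
cosinor fit downward.

## Feature selection

Daily features are aggregated to person level by the within-person mean,
and each candidate is scored by the univariate one-way ANOVA F statistic
against the outcome (for two groups, the squared pooled-variance t).
Candidates are accepted greedily in descending F order — ties broken
lexicographically for determinism — skipping any candidate whose absolute
Pearson correlation with an already-accepted feature is ≥ 0.70, until 3 are
accepted. Perfect separation (zero within-group variance) is guarded to a
large sentinel and flagged rather than returning infinity.

Selection on the full sample deliberately reproduces a known limitation of
small-cohort analyses — it leaks outcome information into every
cross-validation fold and biases performance upward. The package keeps this
as the default for comparability and offers honest within-fold re-selection
(`selection_scope = "within_fold"`, or `select =` in `loso_cv()`) for
leak-free evaluation.

## Classification model

Day rows inherit the person's label. For each leave-one-subject-out fold:

1. a Yeo-Johnson transform is fitted per feature **on the training rows
   only** (λ by Gaussian profile maximum likelihood over [−5, 5], then
   centring/scaling with training moments) and applied to both sides.
   Fitting on the pooled data is available (`pool_transform = TRUE`) only
   to emulate analyses that transformed before splitting;
2. a gradient-boosted tree classifier (xgboost, binary logistic objective,
   exact tree method, single thread for determinism) is trained on
   everyone else's days;
3. the held-out participant's day probabilities are averaged into one
   person-level predicted probability.

Hyperparameters can be tuned per fold by randomized search (default 25
draws over depth {2,3,4}, learning rate {0.01,0.05,0.1,0.3}, rounds
{25,50,100,200}, row/column subsampling {0.7,1}, minimum child weight
{1,5}), scored by person-level AUC under grouped 3-fold inner CV — grouping
by participant so tuning cannot leak within-person information. The
search space is a small-data-appropriate default; the original analysis's
grid is not recorded. The untuned mode (depth 3, η 0.1, 100 rounds) exists
for fast permutation baselines and property tests. Every fold carries a
programmatic guard asserting the train/test participant sets are disjoint,
and all randomness (search draws, tree subsampling, permutations,
bootstraps) derives from one user seed.

Confusion metrics threshold person probabilities at 0.5 (configurable; the
source analysis does not state a threshold and 0.5 is the convention).

## Evaluation

AUC uses the Mann-Whitney formulation (ties count ½), identical to the
trapezoidal area under the empirical ROC; its 95% CI is a seeded
percentile bootstrap over persons (2000 iterations — the same machinery as
the between-model comparison, since no analytic CI method is recorded).
Two models' AUCs are compared by jointly resampling shared participants
2000 times and computing the two-sided tail probability of the AUC
difference with the (count+1)/(iterations+1) Monte-Carlo correction, so
p = 0 is never reported.

Attributions are exact tree-path SHAP values computed on each fold's
held-out rows (test-side, matching how the person scores arise); local
accuracy — attributions plus base value equal the margin output — is
asserted per row (default tolerance 1e-5, reflecting float32 accumulation
across trees; a depth-1 toy model satisfies 1e-6). Mean |SHAP| per feature
aggregates across all held-out rows and folds. Information gain is the
per-fold normalized split-gain fraction per feature (computed from the
tree dump), averaged over folds; features never split on get 0. Both
rankings are reported in descending order.

## Discriminant validity

Person-level predicted scores are regressed (OLS) on the outcome flag,
any non-PTSD current diagnosis (1 = present), and age in years
(uncentred), with t-distribution inference at n − k − 1 degrees of freedom
— appropriate at n ≈ 33, where normal-based p-values would be visibly
anticonservative. A significant positive outcome coefficient alongside a
null non-PTSD coefficient indicates the scores track the target construct
rather than mental-health burden generally. The averaged selected features
also enter a logistic model per outcome, summarized by the Nagelkerke
pseudo-\(R^2\) (0 for the null model; driven to 1 under the
quasi-perfect-separation flag, which is detected from fitted probabilities
numerically at 0 or 1 and reported with a warning).

## The synthetic cohort

No participant data are distributed, so `generate_cohort()` builds the
entire study world: by default 33 male veterans, 7 days × 2880 epochs,
diagnosis prevalence 8/33, age 41 ± 5.3 years. Daytime activity is an
individual cosinor (mesor ≈ 200, amplitude ≈ 180 counts, peak 15:00) plus
AR(1) noise (φ = 0.6, SD 60, clipped at zero) — the autocorrelation puts
intradaily variability between the sinusoid (≈ 0) and white-noise (≈ 2)
extremes. Nights are suppressed inside the logged rest interval with a
planted sleep latency, planted high-activity wake bouts totalling the
configured WASO, and sparse sub-threshold movement blips that drive the
fragmentation index. Quality and restfulness are drawn from a person-level
bivariate normal at correlation 0.9 with small nightly jitter, rounded and
clamped to 1–10. PCL-5 totals are normal (controls 20 ± 8, diagnosed
45 ± 8, truncated to 0–80), which lands the ≥31 and ≥38 prevalences near
11/33 and 7/33. The non-PTSD diagnosis is independent of every feature by
default, so discriminant validity holds by construction; a confounding
mode ties it to half the diagnosed effect for probing the regressions.

Diagnosed participants receive signed shifts in exactly the features the
classification models are expected to select — restfulness (−1.5 points),
WASO (+20 min), efficiency (−4 points, realized as extra latency),
fragmentation (+6 percentage points of blip probability), acrophase
(+1 h) — matching the direction of the person-level feature-outcome
correlations the emulated design reports. These defaults are deliberately
strong effects (standardized differences near 1–2), chosen so that ground
truth is recoverable: parameter-recovery and discrimination tests then
certify the *machinery*. Real cohorts show considerably weaker
associations (|r| ≈ 0.2–0.45), so a high AUC on the synthetic defaults
says nothing about achievable real-world performance — that is precisely
why the acceptance surface rests on worked examples, design counts and
statistical limits rather than on reproducing published AUCs. Every
generative parameter is returned by `planted_truth()`; features that
emerge from the interaction of signal, noise and clipping (e.g. IV, IS,
M10) are marked emergent with their expected effect direction.

Between-person heterogeneity (random person effects on mesor, amplitude,
peak time, bed/rise times, WASO, latency, blip rate) is what keeps
person-level feature correlations away from 1 and makes the
leave-one-subject-out problem nontrivial. The generator does not emulate
naps, shift work, off-wrist episodes, light exposure, or
physiologically detailed accelerometry.

## Numerical choices and degenerate inputs

* Cosinor: exact least squares via QR; degenerate designs (times not
  spanning the period) error; constant series → amplitude 0, \(R^2 = 0\).
* IV undefined (reported missing) on a constant day; IS missing with
  fewer than 2 days; RA missing when M10 + L5 = 0.
* Yeo-Johnson on a constant column: λ fixed at 1 with a warning, unit
  scale.
* F-score ties: lexicographic; perfect separation: sentinel 1e12 +
  flag.
* Bootstrap resamples with a single class are skipped (CI) or redrawn
  with capped retries (model comparison).
* Precision with no predicted positives is missing and F1 is 0 by
  convention.
* Probabilities, seeds and draws are deterministic given the user seed;
  derived per-fold seeds stay within 32-bit integer range.

## Problem sizes in the test suite

The suite exercises the full default cohort (33 × 7 days) for the
retained-day count, leave-one-subject-out integrity, permutation null (20
permutations, untuned mode) and 20-seed effect-direction recovery;
Monte-Carlo limits use 2000 replicate days (IV) and 300 replicates (IS);
oracle equivalences use 25–50 random small instances. These sizes were
chosen to estimate each quantity well while keeping the default suite
fast enough to run habitually.

## Known limitations

* The sleep scorer approximates, but does not reproduce, proprietary
  vendor output; all downstream sleep metrics are therefore
  reproducible-by-construction rather than vendor-identical.
* "Circadian rhythm strength" follows this package's definition (cosinor
  \(R^2\)); other operationalizations exist.
* Full-sample feature selection leaks by design (see above); the
  within-fold mode is the honest alternative.
* With ~33 persons, bootstrap CIs on AUC are wide and confusion metrics
  move in steps of whole persons; interpret single-cohort results
  accordingly.
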