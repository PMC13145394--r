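---
title: "Predicting momentary negative affect from passive sensing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting momentary negative affect from passive sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ecological momentary assessment (EMA) asks people to rate their momentary
negative affect (NA) on a schedule — here eight prompts ("beeps") per day at
roughly 2-hour intervals over 14 days, each scored as the mean of eight 1–7
Likert items (sadness, fear, hostility and guilt item pairs), so observed
scores live on the 1/8 grid in [1, 7]. Just-in-time adaptive interventions
would like to *predict* those scores from passively sensed data instead:
smartwatch heart rate, steps and activity states, and smartphone GPS. This
package implements the full chain — stream cleaning, 2-hour block
aggregation, mobility feature construction, a missingness policy, eleven
regression approaches, and a leakage-safe evaluation design — together with
a synthetic cohort generator, so every stage can be validated against known
ground truth without access to clinical data.

The scientific crux the evaluation is built around: momentary NA has a large
stable between-person component. A model can look accurate by merely
learning each person's average. The harness therefore always includes two
intercept benchmarks (global mean; per-person mean) and separates a
known-user scenario from a new-user scenario.

## The synthetic cohort generator

Labels are drawn from a random-intercept model

$$ y_{it} = \mu + b_i + \textstyle\sum_f \beta_f z_f(\text{window}_{it}) +
A\sin\!\big(2\pi(h_{it}-8)/24\big) + \varepsilon_{it}, $$

with person intercepts $b_i \sim N(0, \sigma_b^2)$, AR(1) residuals with
stationary SD $\sigma_\varepsilon$ and lag-1 autocorrelation $\rho$, and
$z_f$ the cohort-standardized *true* feature value of the 2-h window
preceding beep $t$ (computed analytically from the participant's planned
movement timeline, not from the noisy emitted streams). Eight items are
generated as $\text{clip}_{[1,7]}(\text{round}(y^{lat}_{it} + u_j))$,
$u_j \sim N(0, \sigma_{item}^2)$, and averaged — rounding items first and
averaging second (rather than truncating the mean) reproduces the
discreteness and the mild right skew of real EMA scores near the low end of
the scale.

Default calibration, chosen once as the package's study conditions:
$\mu = 2.89$ with $\sigma_b = 0.8$, $\sigma_\varepsilon = 0.7$ (total SD
$\approx 1.06$, intraclass correlation $\approx .57$, typical of momentary
NA in outpatient cohorts), $\rho = 0.3$ (momentary affect is weakly
autocorrelated at 2-h lags; no published estimate exists for this design, so
this is a declared simulation knob, not a calibrated quantity),
$\sigma_{item} = 0.9$, circadian amplitude 0 by default (time-of-day
relevance is documented in this literature but no functional form is, so
the sinusoid exists as a switch, off by default). Missingness rates default
to 20% skipped beeps, 10% watch-off blocks and 5% GPS dropouts — rates that
produce a realistic exclusion flow at cohort scale.

Movement is simulated as a single home plus 2–4 "away" anchor locations per
participant, with 0–2 daily excursions along straight-line paths (walking
below 1.5 km, vehicle above), sparse stay check-ins, and at-home nights —
the simplest structure that genuinely exercises density clustering,
home-stay detection and transition features. What the generator does *not*
emulate: realistic sleep architecture, multi-home living, GPS multipath
noise bursts, device-specific event detection quirks, or informative
(outcome-dependent) missingness. Tests passing on synthetic data therefore
demonstrate the *pipeline's* correctness and the models' statistical
behavior under the stated generative assumptions — not clinical-grade
performance on real cohorts.

A second, model-level simulator (`simulate_modeling_dataset()`) draws
$(X, y, \text{groups})$ directly from the mixed model with continuous
labels. It exists because closed-form checks (expected absolute error of a
centered normal, variance-component recovery) are only exact without the
item grid.

## Sensor preprocessing

**Heart rate** (30-s means every 10 min): non-numeric values and readings
outside the physiological 30–220 bpm range (bounds inclusive) are removed.
Per block we compute mean/min/max/std (population formula; a single sample
has std 0) and minutes in three zones — resting $\le 60$, moderate strictly
between 60 and 100, vigorous $\ge 100$ bpm, following the printed
inequalities of standard resting-HR categorization. Because the stream is a
10-minute grid, sample counts proxy time: zone minutes are
$120 \cdot n_{zone}/n_{window}$, which guarantees the three zones sum to
the block length whenever any sample exists. The alternative (count × 10
min, capped) breaks that conservation property at stream edges and was
rejected.

**Steps and activity** (event-based intervals): events with non-numeric or
negative values, non-positive durations, or cadence above 200 steps/min
(rare even in elite runners) are dropped. Events are apportioned to blocks
by proportional overlap, $v \cdot |e \cap w| / |e|$, which conserves totals
exactly over any partition of time — the property the test suite sweeps.

**GPS** (event-based points): consecutive-point distances use the haversine
formula on a sphere of radius 6,371,000 m (the radius implied by the
clustering eps convention below); speeds are distance over elapsed time. A
point is *stationary* iff speed < 1.4 m/s (walking speed, strict) **and**
distance < 150 m. Stationary points are clustered with DBSCAN using
great-circle distance as a central angle, eps = 100/6371000 (100 m) and
min_samples = 3% of the person's total GPS points, floored at 2 (DBSCAN
degenerates below 2; the normalization adapts the density requirement to
highly variable event-based sampling volumes). The implementation builds
clusters as connected components of core points, with border points joined
to their earliest-timestamp core neighbor — order-invariant by
construction, and verified point-for-point against an independently coded
brute-force DBSCAN.

**Dwell and home.** Event-based traces emit nothing while a person stays
put, so each point is credited with the time to the next point, capped at
30 min (an uncapped rule lets a single point claim hours of silence; the
cap is a declared parameter). The *home cluster* must dominate (by maximal
dwell) at least 4 nights (20:00–06:00 local, fixed UTC+1 offset — the
study-site convention; DST is deliberately ignored) and at least 50% of
assessed nights; otherwise the fallback is the most-visited cluster,
operationalized as greatest total dwell minutes (a raw point count is
sensitive to sampling-rate artifacts). Per block we report distance
travelled (consecutive in-window pairs only; the boundary-crossing segment
is excluded), point count, and dwell-minute sums for home, stationary and
transition points, each point's dwell additionally clipped at the window
end so a block cannot hold more minutes than it contains.

All windows are half-open $[t - 2h, t)$ anchored at the beep completion
time, which prevents double counting across adjacent beeps.

## Missingness policy and inclusion filters

Absence has two meanings. For event-based signals, an empty block most
plausibly means *no event happened*: distance, point count, transition
minutes, steps and all activity minutes are filled with 0, and minutes at
home and minutes stationary with 120 (no location change = the whole block
at the last known place). Absence that signals device failure is instead
marked missing-completely-at-random (MCAR) and imputed in-fold: all five
GPS features when GPS is missing *and* the participant reported travelling
in the last 2 h; all fourteen wearable features when HR, steps and activity
are simultaneously absent (the watch-off signature); the seven HR features
when HR alone is absent (HR is sampled on a grid, never event-based). The
two mechanisms are disjoint by construction, and the travelling flag is
used *only* for this check — never as a model feature — so the predictor
set stays entirely passive.

Participants are excluded, in order: (1) fewer than 7 calendar days with
at least 4 answered beeps; (2) fewer than 50 total GPS points; (3) GPS
missing while travelling in more than 50% of available blocks; (4) rule 1
re-checked after rows missing all passive features are dropped. "Days" are
local calendar days (the alternative, 24-h spans from enrollment, is less
interpretable and was not chosen).

## The model zoo

All eleven approaches implement one contract — `fit(X, y, groups)` /
`predict(X, groups)`, with prediction defined for participants never seen
at fit time:

* **Global / per-person intercepts** — the benchmarks everything must beat.
  Per-person falls back to the grand mean for unseen users.
* **LR, RF, FFNN** (± person-stable features) — population learners:
  ordinary least squares, a ranger random forest, and a from-scratch
  fully-connected ReLU network with a linear output node, trained
  full-batch with Adam on the squared error.
* **MERF (± PS)** — a random forest for the shared nonlinear function plus
  per-person random intercepts, alternating: (a) forest fit on
  $y - b_{g}$; (b) BLUP shrinkage update
  $b_i = \bar r_i\, \sigma_b^2/(\sigma_b^2 + \sigma_\varepsilon^2/n_i)$
  from *out-of-bag* residuals (in-sample residuals let the forest absorb
  the intercepts); (c) EM moment updates of both variance components.
  Variance estimation uses these moment formulas rather than full REML —
  simple and stable at desk scale, with the penalized-likelihood trace
  exposed for audit. The trace is computed from in-sample residuals because
  bootstrap refit noise would otherwise dominate the convergence signal;
  the default tolerance (1% relative change) reflects that percent-level
  jitter. Unseen users get $b = 0$ (cold start). No holdout adaptation is
  offered for MERF: adapting intercepts honestly would require refitting
  the forest, inconsistent with the partial-adaptation scheme below.
* **FFNN + Embedding** — each participant id maps to a dense 32-dimensional
  vector (64 is the other standard choice) concatenated with the scaled
  features; embeddings and weights are learned jointly. New users receive
  the mean embedding row until `finetune_embeddings()` optimizes fresh rows
  on their adaptation data with every other parameter frozen —
  bit-identical before and after, which the tests check with exact
  equality rather than a hash.

Predictions are *not* clipped to [1, 7]: the intercept benchmarks cannot
leave the range, and clipping would silently change MAE comparisons
against them.

Network budgets are config defaults, declared rather than reconstructed:
one hidden layer of 32 units; population nets use Adam at 0.01 for 300
epochs; the embedding net uses 0.1 for 300 epochs (its gradient splits
between dozens of feature columns and the embedding table, and the larger
step is what lets person offsets be learned within the same budget — the
embedding table is the model's whole point) and fine-tunes embeddings at
0.05 for 200 epochs.

## Evaluation design

An outer user split holds out ~10% of participants (at least one),
stratified by per-person row count using quartile bins with
largest-remainder allocation, so the holdout mirrors sampling intensity.
Within every user, the chronologically first 80% of rows (floored) train
and the last 20% test. Hyperparameter search, when enabled, uses grouped
expanding-window cross-validation: five chronological chunks per person,
fold *i* training on everyone's chunks $1..i-1$ and validating on chunk
*i*; the first fold is skipped (its training set would be empty), leaving
exactly four folds. Ties in the grid go to the configuration with fewest
hyperparameters, then grid order.

All preprocessing is fitted strictly inside training rows: a k-NN imputer
(k = 5; nan-Euclidean distances over mutually observed raw columns,
sklearn-style — the method is standard, k is a declared default) fills the
MCAR cells; categoricals are one-hot encoded against the training
vocabulary (unseen levels encode as all zeros); continuous columns with
training skewness above 1 and non-negative support are `log1p`-transformed
(the threshold is a declared operationalization of "right-skewed");
min-max scaling uses training bounds and extrapolates linearly rather than
clipping; columns with (numerically) zero training variance are dropped.

Two scenarios: **known users** (train on first 80%, test on last 20% of
the training cohort) and **new users** (apply the same fitted models to
holdout users' last 20%; only the per-person intercept and the embedding
net first adapt on the holdout users' first 80%, the latter via
embedding-only fine-tuning). Metrics are MAE, RMSE and $R^2$. The $R^2$
baseline is the evaluated split's own label mean — this is what makes a
global-intercept model score $\approx 0$ (slightly negative in finite
samples) and is the default; the training-mean baseline is available as a
switch (`r2_baseline = "train"`), since either convention appears in this
literature.

## Numerical and degenerate-input choices

Inclusive HR bounds; strict stationary inequalities; population std with
single-sample windows at 0; zero-length events rejected at aggregation
(cleaning removes them first); duplicate GPS timestamps flagged degenerate
and excluded from speed computation, inheriting the previous movement
state; empty windows yield missing flags, never zeros; a cluster set with
no clusters leaves home-dependent features missing for that participant;
single-participant MERF degenerates to a plain forest with a warning;
empty embedding adaptation sets leave the new rows at the mean-embedding
initialization with a warning. All stochastic components (cohort
generation, missingness injection, holdout draw, forest bootstraps,
network initialization) consume named seeds derived from one master seed.

## Problem sizes used in validation

The packaged validation suite runs, among others: MERF parameter recovery
at 60 participants × 80 blocks averaged over 5 seeds (intercept
correlation ≥ .9, $\sigma_b^2$ within 25%); benchmark calibration against
the closed forms $\sigma_\varepsilon\sqrt{2/\pi}$ and
$\sqrt{\sigma_b^2+\sigma_\varepsilon^2}\sqrt{2/\pi}$ at 100 × 100;
personalization-ordering sweeps over 10 seeds at 30 × 40 in both a
high-ICC/zero-signal and a strong-signal regime; 1,000 random split draws
for the leakage invariants; 50 random instances against the brute-force
DBSCAN oracle; and an end-to-end run on a 30-participant cohort producing
the full 11-model × 2-scenario table. These sizes were chosen as the
smallest at which the checked statistical properties are stable.

## Known limitations

The generator's excursion geometry is deliberately simple (straight paths,
one home); features derived from it are easier to cluster than real urban
traces. The MERF uses moment/EM variance updates, not REML, and random
intercepts only — no random slopes. The embedding net is a small MLP, not
a tuned deep model; its budgets are defaults, not the result of a search
protocol. Weather enters as a single-site daily table. Sequential models
and multiverse-style sensitivity analyses are out of scope.
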