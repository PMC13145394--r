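# affectsense

Predicting **momentary negative affect (NA)** from passively sensed
smartphone and smartwatch data, end to end: sensor-stream cleaning,
EMA-aligned 2-hour block aggregation, GPS mobility features, a principled
missingness policy, eleven regression approaches under one fit/predict
contract, and a leakage-safe evaluation harness — plus a synthetic cohort
generator with known ground truth so the whole chain is testable without
clinical data.

**Who it is for.** Researchers in digital phenotyping / ambulatory
assessment who want to benchmark passive prediction of momentary affect
against the benchmarks that actually matter (intercept-only models), and
methodologists who need a tested reference implementation of the pipeline
pieces: proportional-overlap aggregation, DBSCAN-based home/stay
detection, mixed-effect random forests, and embedding-personalized
networks with cold-start adaptation.

## The core models

Momentary NA (mean of eight 1–7 items, predicted at time *t* from features
of the window *[t−2h, t)*) is modeled eleven ways, from benchmarks upward:

- **Global / Per-person intercept** — ȳ, or ȳᵢ per participant (grand-mean
  fallback for unseen users).
- **LR, RF, FFNN** (± six person-stable covariates) — population learners.
- **MERF** (± PS) — random forest `f(x)` plus random intercepts `bᵢ`
  estimated by an EM-style alternation with BLUP shrinkage
  `bᵢ = r̄ᵢ · σ²_b / (σ²_b + σ²_ε/nᵢ)` on out-of-bag residuals and
  moment updates of `σ²_b`, `σ²_ε`; prediction `ŷ = f(x) + b_g` with
  `b = 0` for new users.
- **FFNN + Embedding** — a learned dense vector per participant id,
  concatenated with the sensor features; new users adapt by optimizing
  *only* their embedding rows while every network weight stays frozen.

Evaluation uses a stratified ~10% user holdout plus per-user chronological
80/20 splits, expanding-window cross-validation (5 chunks, first fold
skipped → 4 folds), in-fold k-NN imputation / one-hot encoding / log +
min-max scaling, and MAE / RMSE / R² in two scenarios: *known users*
(time-based holdout) and *new users* (cold start, with adaptation only for
the per-person intercept and the embedding net).

## Worked example

```r
library(affectsense)

run <- run_pipeline(n_participants = 30, seed = 1)
subset(run$results, scenario == "time")[, c("label", "mae", "r2", "rmse")]
```

```
                  label   mae      r2  rmse
           Global Intercept 0.808  -0.001 0.988
       Per Person Intercept 0.632   0.390 0.771
                         LR 0.818  -0.026 1.000
                         RF 0.786   0.036 0.969
                       FFNN 0.838  -0.101 1.036
                    LR + PS 0.782   0.039 0.968
                    RF + PS 0.649   0.340 0.802
                  FFNN + PS 0.856  -0.151 1.059
                       MERF 0.633   0.379 0.778
                  MERF + PS 0.639   0.367 0.785
           FFNN + Embedding 0.652   0.336 0.805
```

Reading this: the global intercept sets the floor (R² ≈ 0 by
construction); the per-person intercept alone removes ~22% of its MAE,
because most predictable variance in NA sits in stable between-person
differences (`run$icc` here is 0.45). The personalized models — MERF and
the embedding net — match that benchmark almost exactly under the weak
feature–outcome coupling the default generator plants, while the purely
population-based learners barely improve on the grand mean. In the
new-user scenario the same pattern sharpens: only the two adapted models
(per-person intercept MAE 0.588, FFNN + Embedding 0.579) track new users,
everything else hovers near the global intercept (0.96).

Each stage is also usable on its own:

```r
cfg    <- synthetic_config(n_participants = 12, seed = 3)
bundle <- inject_missingness(generate_cohort(cfg))
blocks <- build_blocks(bundle)                      # clean + aggregate
filt   <- apply_inclusion_filters(blocks)           # ordered exclusions
ds     <- assemble_dataset(apply_missingness_policy(filt$blocks),
                           bundle$participants, variant = "with_PS")
merf   <- fit_merf(predict(fit_preprocessor(ds$X), ds$X), ds$y, ds$groups)
```

See `vignettes/methods.Rmd` for the generative model, every preprocessing
rule with its rationale, the missingness policy, and the numerical choices.

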