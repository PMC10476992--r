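# linacsched

Radiotherapy linear accelerators (linacs) are scarce and expensive, and a
large share of their workday is lost to booking slack: appointments are
conventionally booked into fixed equal-length slots (the *block method*),
although the true duration of a fraction — patient positioning time (PT)
plus irradiation treatment time (TT) — varies from roughly 15 to 22 minutes
for routine fractions and 25 to 30 minutes for a course's first fraction.
`linacsched` implements the alternative: predict each patient's PT and TT
from positioning and plan-complexity features, and pack the predicted
durations into a minute-granular schedule so that the remaining capacity of
every hour is explicit and usable.

The package is aimed at medical-physics and radiotherapy-operations
researchers who want to study duration-aware scheduling on synthetic
cohorts, end to end.

## What it does

* **Synthetic cohorts** — reproducible patient-fraction records with
  categorical positioning features (immobilization site and board,
  six-dimension table, vacuum cushion, metallic implant, IGRT) and
  plan-complexity features (treatment site, irradiation technology 2D /
  3D-CRT / IMRT / VMAT / SBRT, prescription dose 2–12 Gy per fraction,
  0–1024 control points), with integer-second PT/TT drawn from an additive
  generative model calibrated to the operational duration windows above.
* **Deep feature synthesis (DFS)** — recursive feature generation over a
  relational entity set. Entity primitives (`efeat`) transform single
  columns, relational primitives (`rfeat`: count, sum, mean, min, max, std)
  aggregate child tables over backward (one-to-many) relationships, and
  direct features (`dfeat`) copy parent attributes over forward
  (many-to-one) relationships, recursively toward the target table.
* **Auto-ML duration models** — the selected model is
  `A* = argmin_A (1/K) Σᵢ L(A, D_train⁽ⁱ⁾, D_valid⁽ⁱ⁾)` over a candidate
  family (linear, ridge, decision tree, random forest, optional gradient
  boosting), followed by hyperparameter tuning
  `λ* = argmin_λ (1/K) Σᵢ L(A_λ, …)` with the same K-fold objective.
* **Tolerance-band accuracy** — `acc(T) = (1/n) Σₚ 1[|x̂ₚ − xₚ| ≤ T]`,
  reported over the grid T ∈ {30, 45, 60, 75, 90, 105} seconds.
* **Regression baseline** — the conventional coded-predictor models
  `Yp = C₁ + α₁X₁ + α₂X₂ + α₃X₃` and
  `Yt = C₂ + β₁X₁ + β₂X₂ + β₃X₃ + β₄X₄` (X₁ treatment-site code, X₂
  first-fraction flag, X₃ technique code, X₄ machine modulation), shipped
  with the published reference coefficient sets
  (C₁ = 3.551, α = −0.0154, 0.18287, 0.3846;
  C₂ = 3.5518, β = −0.0569, 0.3962, 0.0014, 0.496), in minutes.
* **Minute-granular scheduler** — a day (default 08:00–18:00) tiles into
  1-h "Slot L" blocks of sixty 1-minute "Slot S" unit slots; a daily
  machine-QA reservation precedes treatment; appointments occupy contiguous
  unit-slot runs of exactly their predicted length (first-fit or best-fit);
  every block carries a green/orange/red remaining-capacity indicator
  (green > 20 free min, red < 5, orange otherwise); weekend-only QA and
  maintenance tasks are admitted or rejected by placement rules; and a
  fixed-block booking baseline is provided for utilization comparison.

## Worked example

```r
library(linacsched)

res <- run_pipeline(default_run_config(), output_dir = "demo")
#> generates 1665 records, splits 1165/500, synthesizes features,
#> selects and tunes PT/TT models, evaluates, schedules, compares.

res$accuracy$automl$pt
#>   threshold_s accuracy
#> 1          30    0.878
#> 2          45    0.982
#> 3          60    0.996
#> 4          75    1.000
#> 5          90    1.000
#> 6         105    1.000

res$accuracy$mlr_baseline$pt$accuracy[1:3]
#> [1] 0.770 0.940 0.986

head(res$predictions, 3)
#>   patient_id predicted_pt_s predicted_tt_s predicted_total_s
#> 1     P00002       530.0567       686.5365          1216.593
#> 2     P00005       534.6836       667.3099          1201.993
#> 3     P00012       507.9626       661.3180          1169.281

sum(res$minute_day$appointments$assigned)   # patients packed into one day
#> [1] 27
free_minutes(res$minute_day)                # leftover capacity, minutes
#> [1] 29
```

The accuracy tables say: within a 30-s tolerance the selected model places
87.8% of test-set positioning times, against 77.0% for the coded-predictor
baseline; by 75 s both are at 1.0 on this synthetic cohort (the generative
model is additive, so the feature-based learner can represent it almost
exactly — real clinical data are harder). The schedule packs 27 predicted
appointments into the 580 bookable minutes of a 10-h day after the 20-min
daily QA, leaving 29 free minutes visible for short tasks.

The baseline evaluated at all-zero codes returns its intercepts exactly:

```r
mlr_predict_pt(default_pt_coefficients(), data.frame(X1=0, X2=0, X3=0))
#> [1] 3.551
mlr_predict_tt(default_tt_coefficients(), data.frame(X1=0, X2=0, X3=0, X4=0))
#> [1] 3.5518
```

A thin command-line interface over the same functions ships with the
package (`simulate-cohort`, `featurize`, `train`, `predict`, `evaluate`,
`schedule`, `compare`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","linacsched.R",package="linacsched"))')" \
  run --out demo
```

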