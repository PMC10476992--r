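---
title: "Methods: duration prediction and minute-granular linac scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duration prediction and minute-granular linac scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A radiotherapy course delivers 25–33 fractions on sequential workdays, and
each fraction occupies the linac for its positioning time (PT — patient
immobilization plus position verification) and treatment time (TT — dose
delivery). Booking by fixed equal-length slots wastes the difference
between the slot and the true service time and hides the remaining
capacity of the day. `linacsched` implements the duration-aware
alternative: learn per-fraction PT and TT from positioning and
plan-complexity features, and book the *predicted* duration, minute by
minute. This vignette records the models, the default parameters and why
they hold their values, and the design decisions taken where the design
was genuinely open.

## The synthetic cohort generator

No public per-fraction duration dataset exists at this granularity, so the
package generates its own study material. A record carries the categorical
positioning features (immobilization site and board, six-dimension table,
vacuum cushion, metallic implant, IGRT yes/no), the plan features
(treatment site; technology 2D / 3D-CRT / IMRT / VMAT / SBRT; prescription
dose in Gy per fraction, 2–12; control points, 0–1024), a first-fraction
flag, and integer-second true PT and TT. Seconds are the canonical unit
throughout the package; minutes appear only at the scheduler and report
boundaries, matching how treatment-record systems log start/stop stamps.

Durations come from an additive model: a base duration per phase plus a
fixed number of seconds per feature level, per Gy, and per control point,
Gaussian noise (`noise_sd`, default 20 s per phase), rounding to whole
seconds and a 60-s floor. The defaults were chosen once, from the
operational windows a radiotherapy service quotes — 15–22 min total for a
routine fraction, 25–30 min for a first fraction — so that deterministic
totals span about 18.4–21.4 min and the first-fraction surcharge
(`first_fraction_extra`, 450 s of extra positioning) lands first fractions
near 26–29 min; with the default noise both strata sit inside their
windows with probability well above 0.95, which the test suite verifies
empirically at n = 10,000.

Feature distributions are deliberately neutral: uniform over categorical
levels, 0.5 for binary flags, dose uniform on [2, 12] Gy rounded to
0.1 Gy, and control points uniform within a per-technology range (low for
2D/3D-CRT, high for modulated deliveries) — the generator makes no claim
to reproduce any particular clinic's case mix, and every distribution is
overridable in `cohort_config()`. Two couplings are kept because their
absence would be clinically incoherent: the immobilization site mirrors
the treatment site, and the SBRT board accompanies the SBRT technique
(both overridable). The first-fraction rate defaults to 0.04 since a
25–33-fraction course makes roughly one record in 28 a first fraction.

What the generator does *not* emulate: arrival processes, no-shows,
day-to-day correlation within a course, therapist effects, interactions
between features, or heavy-tailed service times. Because the truth is
additive and the features are fully observed, a linear learner can
represent it almost exactly — so the high tolerance-band accuracies on
synthetic cohorts demonstrate pipeline correctness, not clinical
attainability.

## Feature synthesis

Features are generated by recursive deep feature synthesis over a
relational entity set. Three primitive classes exist: entity transforms
(`efeat`) computed per entry of a column; relational aggregations
(`rfeat`) over a backward (one-to-many) relationship, grouped by the
parent key; and direct features (`dfeat`) copied over a forward
(many-to-one) relationship. The recursion visits child tables first and
aggregates them in, then unvisited parent tables and copies them in, and
applies entity transforms last — so transforms of aggregates (a z-scored
mean, say) appear at depth ≥ 2.

Open points resolved here, all configurable:

* **Primitive vocabulary** — `count`, `sum`, `mean`, `min`, `max`, `std`
  for aggregation; `identity` and `zscore` for transforms. `zscore` uses
  the population standard deviation; `std` the sample one.
* **Empty aggregates** — a parent with no children receives 0 from
  `count` and the missing marker from every other aggregation.
* **`max_depth` defaults to 2** — unbounded recursion diverges on cyclic
  schemas; cycles beyond the limit are truncated with a log entry.
* **Visited-set discipline** — a shared visited set guarantees no table is
  imported twice along any path. Recursion is also skipped into
  already-visited *child* tables (aggregation is still applied):
  re-entering one would regenerate columns under duplicate names and break
  the stable-naming guarantee.
* **Determinism** — tables and columns are processed in declaration
  order; feature names encode their provenance
  (`MEAN(fractions.prescription_dose)`, `patients.igrt`), and a name that
  already exists is never regenerated.
* **Encoding** — categorical and logical columns are one-hot encoded up
  front (keys and foreign keys excluded); `feature_design()` produces the
  numeric modeling matrix, imputing missing markers (z-score of a constant
  column, empty-aggregate means, dangling keys) as zero, which leaves the
  affected column inert in a fit.

For the radiotherapy application the default entity set has two tables —
`patients` (static positioning/plan features) and `fractions`
(first-fraction flag, dose, control points), linked fractions → patients
with `fractions` as target. This decomposition is a documented assumption,
not an observed fact about any clinic's database. True durations are
never part of the entity set.

## Duration models

PT and TT models are trained independently and summed at prediction time
(`predict_total_duration()`, floored at 120 s as a guard against
extrapolation below plausible service times). Model selection minimizes
the mean K-fold cross-validation loss over a candidate family; tuning then
minimizes the same objective over the winner's hyperparameter grid. Open
points resolved here:

* **Loss** — mean absolute error by default (aligned with the
  tolerance-band evaluation); MSE selectable.
* **K = 5** folds; fold assignment is a seeded random permutation, shared
  by every candidate so losses are comparable.
* **Candidate family** — linear regression (QR least squares, aliased
  columns dropped), ridge (glmnet, λ ∈ {0.01, 0.1, 1}), decision tree
  (rpart, cp ∈ {0.001, 0.01, 0.05}), random forest (ranger, 100 trees,
  single-threaded and seeded for reproducibility, minimum node size
  ∈ {5, 20}). A gradient-boosted candidate (xgboost) exists but is off by
  default; shallow neural candidates were deliberately excluded — on
  additive synthetic data they cannot beat the linear family and their
  fits are the least reproducible across platforms.
* **Ties** break by declaration order; grids larger than the evaluation
  budget are subsampled deterministically under the run seed.

The conventional baseline is a pair of least-squares regressions on coded
predictors: treatment-site code X₁, first-fraction flag X₂, technique code
X₃, and machine modulation X₄ (TT only). The coding is integer, in
feature-declaration order, and lives in one exported map
(`predictor_coding_map()`); any fixed coding reproduces the shipped
intercept checks. "Machine modulation" is not precisely defined in the
source material; it is realized as a binary modulated-delivery indicator
(IMRT/VMAT/SBRT = 1). The shipped reference coefficients are in minutes —
their magnitudes (≈ 3.5) only make sense on that scale against 5–25-min
durations — and `minutes_to_seconds()` converts at the module boundary.
In the pipeline the baseline is refitted to the training split; a coded
predictor that happens to be constant there (e.g. no first fractions in a
small cohort) is dropped with zero weight rather than failing the rank
check that the strict `fit_mlr()` enforces.

Prediction quality is summarized by the tolerance-band accuracy
`acc(T) = (1/n) Σ 1[|x̂ − x| ≤ T]`, with an inclusive boundary, over
T ∈ {30, …, 105} s. The statistic is non-decreasing in T by construction;
the tests pin it to a brute-force indicator count.

## The scheduler

A day is tiled by "Slot L" blocks (default 60 min) of 1-min "Slot S" unit
slots; a window not divisible by the block length yields a final short
block, logged. Appointments are ceiled to whole minutes, may not span
block boundaries by default (a flag permits it), and are placed first-fit
(best-fit selectable). Failure to place is a reported outcome, never an
exception. The daily machine QA precedes the first treatment; its default
of 20 min reflects the worked operational example, and values are
validated against the 10–20-min range quoted for daily checks. Available
time is always computed from first principles (total minus reserved): a
10-h day minus a 20-min QA leaves 580 bookable minutes.

The capacity indicator is green above 20 free minutes, red below 5,
orange below 10 — and the band 10–20 min, which the verbal rule leaves
unspecified, also maps to orange: such a block can absorb short tasks but
not a routine appointment, so the conservative flag is the useful one.
Red takes precedence below 5 (the verbal thresholds overlap); the rule is
total over every free count, which a test checks exhaustively.

Non-treatment tasks carry catalog durations and placement rules: daily QA
10–20 min before treatment on workdays; weekly/monthly/annual QA (2–4 h),
routine maintenance (60–90 min) and periodic maintenance (2 h) on
weekends — rejected from workday schedules as a reported outcome;
dosimetry verification (5–8 min) and breakdown repair anywhere. Tasks
longer than one block may span block boundaries, since a 75-min
maintenance could otherwise never be placed in 60-min blocks. Emergency
capacity lookup returns the green block with the largest free run; no
displacement of scheduled patients is attempted, because no displacement
policy is defined in the source material.

The comparison baseline is the block method: sections (default 60 min) of
four equal fixed slots, one whole slot per appointment regardless of
predicted duration. When every duration fits the fixed slot, minute-based
packing provably books at least as many patients (each fixed slot's
appointment also fits the corresponding minutes), and the tests check this
dominance on 200 randomized cohorts. When predicted durations *exceed*
the fixed slot — the default cohort's ~19-min fractions against 15-min
slots — the block method books more patients only by silently overrunning
its slots; the utilization report counts bookings, not overruns, so the
comparison must be read with the slot length in mind.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains cohort → features → split → train → predict →
evaluate → schedule → compare, writing six artifacts plus a manifest
(package version, seed, config hash, record counts). One seed governs
every stochastic stage (generation, splitting, folds, forest fits);
stage-local seeds are small fixed offsets of it. Two runs with identical
configuration produce byte-identical artifacts, which the tests assert at
the default scale (1665 records, 1165/500 split) and on a reduced
configuration. The default test suite works at desk scale — cohorts of
90–10,000 records, toy entity sets of up to 20 rows per table, 200
Monte-Carlo replicates for coefficient recovery, 200 randomized scheduling
cohorts — sizes chosen so the whole suite runs in a couple of minutes
while every property still has statistical room to fail.

## Known limitations

* The generator's additivity flatters feature-based learners; passing
  accuracy tests says nothing about accuracy on real clinical data.
* Single linac, single day: no multi-day course locking (the block
  method's same-slot-every-day behaviour is not modeled), no patient
  preferences, no queueing beyond the prediction error already embedded
  in durations.
* The entity-set decomposition for the cohort is an assumption; richer
  schemas (courses, plans, QA results as tables) would exercise deeper
  recursion than the shipped default.
* CBCT vs EPID image guidance is collapsed to a binary IGRT flag, as in
  the feature value domain.
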