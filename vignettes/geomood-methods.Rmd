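---
title: "Mobility features from geolocation for depression detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobility features from geolocation for depression detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomood)
```

`geomood` turns raw smartphone location streams into weekly mobility
features and a cross-validated classifier of depressed weeks. This
vignette records the model, the assumptions, and the design decisions a
maintainer would want to know — including the places where the design was
genuinely open and we had to choose.

## Data model and coordinate frame

A trace is a tibble of timestamped fixes. All internal computation happens
in a planar km frame: geographic degrees are projected equirectangularly
about a reference point (the first fix by default), with 111.195 km per
degree of latitude and a cos(latitude) factor for longitude. Every
threshold in the pipeline (0.01 km stationarity, 0.5 km imputation radius,
0.4 km cluster separation, 100 km/h speed cut) presumes metric distances;
the equirectangular choice keeps the projection exactly invertible and its
error against great-circle distance is below 0.5% for offsets under 50 km
at latitudes below 70°, far inside the city scale the method operates on.
Absolute position is immaterial — traces are typically anonymized relative
to an arbitrary reference — because every feature depends only on relative
coordinates after recentering on the inferred home.

Clock-time rules (the overnight home window, the 21:00 imputation clause,
weekday/weekend subsets, Monday-00:00 calendar weeks) are evaluated in a
configurable timezone, UTC by default.

## Preprocessing

Three stages, with all tunables surfaced in `preprocess_params()`:

* **Speed filtering** (`v_max = 100` km/h). A fix is flagged when the
  speed from its predecessor or to its successor exceeds `v_max`.
  Low-accuracy fixes from fused location providers share *exact*
  coordinates, so any exact coordinate accumulating `burst_min_count = 3`
  flagged fixes is treated as an artifact location and all its fixes are
  removed. Flagged fixes at non-repeating coordinates are deliberately
  kept: when artifacts interleave with the true stream, the true fixes on
  either side of every artifact are themselves speed-flagged, and removing
  them would throw away genuine data. On the synthetic reference cohort
  this rule removes 100% of injected artifacts and no true fixes.
* **Downsampling** to 12 samples/h. Hours are clock-aligned; an epoch
  whose per-axis SD is below `stationary_sd_km = 0.01` collapses to its
  mean on all 12 grid slots, otherwise each slot takes the coordinate-wise
  median of fixes within ±2.5 min. Slots without fixes are missing. The
  output is a regular 5-min grid with NA for missing slots — one
  representation for both "no data in the window" and "no data in the
  hour", which simplifies everything downstream.
* **Imputation.** A missing run is filled with its flank mean iff the
  flanks are within 0.5 km of each other and the run is ≤ 2 h at any time,
  or ≤ 12 h starting at or after 21:00 local. "Starting" means the first
  missing slot's clock time; runs crossing midnight qualify by their start.
  Whether the overnight clause should test the gap's start, end, or any
  overlap is not determined by the method's description; the start
  convention is the most conservative for evening gaps and is isolated in
  the parameters.

## Places

Stationary/transition segmentation computes three 10-min moving averages
of the instantaneous speed (centred, backward, forward) and marks a sample
transitioning when any exceeds `d = 1.5` km/h. Speeds are assigned to
intervals between adjacent grid slots, and a window averages the interval
speeds whose midpoints it contains — the discretization of the moving
integrals is not otherwise pinned down, and this one makes the three
windows exact unions of grid intervals. Intervals spanning missing slots
carry no speed; windows use whatever content exists.

Clustering grows K from 1, fitting seeded K-means++ at each K, and accepts
the largest K whose fitted centers all stay ≥ `l = 0.4` km apart. Ties and
restarts are deterministic given the seed. Clustering is fit per analysis
window (the calendar week and its subsets), so the cluster count NC is
week-local; home inference, by contrast, uses the participant's full trace:
per day the modal 0.01-km coordinate bin of the 02:00–07:00 samples is the
day's home candidate, the modal candidate over days (ties to the earliest
occurrence) is home, and the trace is recentered so home is the origin.
The 0.01 km bin matches the stationarity SD scale; the mode of a
continuous coordinate needs some bin.

## Features

Ten features per week × five subsets = 50 values, natural logs throughout
(the normalized entropy is base-invariant and the downstream models are
scale-free):

* ENT/NENT over cluster occupancy proportions, computed on *stationary*
  samples only — transition time is its own feature, and occupancy "time in
  cluster i" is ambiguous about travel; NENT is clamped at 1 against
  floating-point overshoot of `ln N`.
* LV = ln(var x + var y) with a 1e-10 km² floor so constant weeks stay
  finite.
* HS: share of non-missing samples in the home cluster — the cluster whose
  center is nearest the origin, required within `l`; a week wholly away
  from home scores 0.
* TT: share of transitioning samples; HS + other-cluster share + TT = 100%
  exactly.
* TD: summed distances between adjacent non-missing slots; segments
  spanning gaps are skipped rather than bridged.
* DM/DMN/DMD: mean Lomb–Scargle power over 25 frequencies evenly spaced in
  frequency across wavelengths 23.5–24.5 h, of the raw coordinates, the
  per-axis standardized coordinates, and the standardized distance from
  home. The periodogram is the classic tau-offset Lomb form and is
  deliberately *unnormalized* (no division by the series variance): the
  raw-coordinate feature DM is supposed to respond to the magnitude of
  movement — scaling all coordinates ×10 raises DM by exactly ln 100 —
  while DMN and DMD, computed on unit-variance signals, are scale-free.
  Band powers are floored at 1e-10 before the log. 25 grid frequencies
  resolve the narrow band without measurable cost; the band endpoints are
  part of the feature's definition.

### The rotation geometry of DM, DMN and DMD

A point worth recording because it contradicts a common intuition: the
Lomb–Scargle power at a frequency is a quadratic form `uᵀQu` in the
(centred) signal, with `Q` depending only on the sample times. The sum of
the two axis powers is therefore `tr(XᵀQX)` for the n×2 coordinate matrix
X, and is *exactly* invariant under any rotation `X → XR` — so DM cannot
distinguish a person commuting due north from one commuting north-east, to
machine precision, and our tests assert this invariance rather than the
opposite. The direction sensitivity that motivates the distance-from-home
variant is real, but it lives in DMN: standardizing each axis to unit
variance breaks the quadratic form, and the north vs north-east travellers
differ in DMN by exactly ln 2 (one axis carrying all the power vs two
axes carrying half each). DMD is invariant by construction, which is the
point of computing it on the distance from home.

### Subsets

Base (whole week), weekday (Mon–Fri), weekend (Sat–Sun), median (the
median of each feature over base, weekday, weekend, and the seven
leave-one-day-out weeks; missing constituents are dropped from the
median), and the optimized daily-exclusion subset, which removes days with
`d_i > median(D) + α·σ_D` where `d_i` is the day's maximum distance from
home. α defaults to 1; `optimize_alpha()` implements the per-feature grid
search (default grid 0–3 in 0.25 steps) maximizing the training-set
accuracy of a single-feature logistic classifier. Because only a handful
of distinct day-exclusion sets exist per week, the feature table
precomputes the optimized-subset features for every grid α
(`alpha_grid =`), making fold-confined optimization a cheap lookup.
Optimizing α on all data would leak test labels into the features; the
package's design confines it to training folds, and the precomputed table
lets a user reproduce the leaky variant deliberately if they want the
comparison.

Weeks must have ≥ 50% of grid slots non-missing on ≥ 4 distinct days to
enter the feature table; the sufficiency threshold is configurable since
the underlying notion ("sufficient data to calculate features") is not
quantified anywhere authoritative.

## Labels

A week is labeled by a single QIDS response within 3.5 days either side of
it, or — when two or more responses fall within 7 days either side — by
the mean of the linear interpolation evaluated at the week's seven local-
noon day midpoints, held constant beyond the first/last response. The
depression threshold is score ≥ 11. With weekly-cadence responses the
interpolation branch dominates and labels blend neighboring weeks'
scores near mood transitions; this is a property of the labeling rule
itself, visible in the synthetic cohort as label noise concentrated at
episode boundaries.

## Models and evaluation

* Linear score model: ordinary least squares.
* Quadratic logistic GLM: `Q = a / (1 + exp(−(β₀ + β₁f + β₂f²)))` with
  `a = 27`, the QIDS ceiling — the natural choice for a score bounded by
  the instrument, though nothing in the method pins `a` down. Fitting is
  nonlinear least squares from five deterministic starts (features are
  standardized internally for conditioning; coefficients are reported on
  the standardized scale with the centering recorded). Predictions are
  clamped microscopically inside (0, a) where the link saturates in
  floating point.
* QDA: class-conditional Gaussians with per-class covariance, equal priors
  (training sets are equalized), and a ridge of `1e-6·tr(Σ)/d` when a
  covariance is ill-conditioned. The implementation is cross-checked
  against an independent reference in the tests.
* Metrics: accuracy, sensitivity, specificity, the harmonic mean
  `F1 = 2·Se·Sp/(Se+Sp)` (named `f1_sesp` because it is *not*
  precision-recall F1), ROC by threshold sweep, AUC by trapezoid.

Cross-validation schemes: leave-one-participant-out; k-fold over
participants (k ∈ {5, 10}, partitions regenerated ⌈N/k⌉ times, stratified
so folds contain depressed-week participants where possible); and
within-participant 3-fold, which interleaves each participant's weeks
(1,4,7…/2,5,8…/3,6,9…) to balance time coverage and deliberately allows a
participant to appear in training and test — its accuracy advantage over
participant-wise schemes measures the non-independence of a participant's
weeks. For classification, each fold's training set is rebalanced M = 100
times by keeping all minority weeks and subsampling the majority; one
equalization iteration pools the test predictions of all folds, and
results are the median and IQR (Q3 − Q1) over iterations. The mean ROC
curve is a vertical average over a common FPR grid. Wrapper feature
selection is greedy forward search scored by median F1 (or MAE), ties to
the earliest candidate in canonical column order, with fresh seeded
equalization per candidate evaluation.

A permutation sanity check accompanies the classification result: globally
shuffling week scores destroys the feature–label association and should
leave AUC near 0.5. Shuffling *within* participants is not a valid null
here — it preserves each participant's label composition, and since both
mood and mobility persist within participants, participant-level
association alone yields AUC ≈ 0.7. Because participant clustering gives
the global-shuffle AUC a spread of roughly ±0.1 on 20 participants, the
acceptance check medians five shuffle replicates.

## The synthetic cohort

`synthetic_config()` defines the reference study conditions: 20
participants × 10 weeks, a home at the origin, 6 recurrent places 1–10 km
away, overnight home residence (00:00–07:00 always), and a two-state
weekly Markov mood chain with stationary depressed fraction 0.3 and
persistence 0.85 — mean episode length ≈ 6.7 weeks, chosen because
bipolar depressive episodes last weeks to months and short episodes would
make the weekly interpolated labels disproportionately noisy at
transitions. Depressed weeks raise the whole-day home-stay probability
(0.55 → 0.90), shrink the weekly place pool (4 → 2), visit fewer places
per outing (2–3 → 1) and widen departure-time jitter (0.75 h → 2.5 h SD).
QIDS scores draw from N(6, 2²) clamped to 0–10 in well weeks and
N(16, 3²) clamped to 11–27 in depressed weeks, so the flag and the ≥ 11
threshold agree by construction; one response is emitted per week within
48 h of the week's end. No quantitative effect sizes exist to copy from
real cohorts — these defaults are the package's own, labeled as such, and
they encode only the directional structure the method presumes (more home
stay, fewer places, less travel, less routine when depressed).

Measurement pathology is generated on top: fixes at a mean 120 s interval
(60 s SD — a desk-scale rate, not a device-specific one) with 5 m GPS
noise; two artifact bursts per day of five identical fixes offset 10 km
from the concurrent true position, interleaved with the true stream 10 s
after consecutive true fixes (a contiguous same-coordinate run would leave
its interior fixes speed-unflagged, which is not how interleaved
low-accuracy fixes behave); and two missing segments per week of 1–6 h.
Occasional "far days" (10% of weeks, 30 km) provide the outliers the
daily-exclusion subset targets. Every generated quantity — week states and
scores, true home, place sets, per-fix artifact flags, gap windows,
scheduled home-time fractions — is retained in a truth ledger so each
pipeline stage has an oracle.

What the generator does **not** emulate: road networks (travel is
straight-line at 25 km/h), accuracy fields, device heterogeneity,
multi-home living, work places with overnight stays, or any coupling from
behavior back to mood. Passing tests on this cohort therefore show the
pipeline recovers the structure it assumes, under measurement noise it
models — not that real cohorts are this separable. The reference cohort's
cross-validated F1 (~0.9) sits near, and somewhat above, the operating
point reported for real bipolar cohorts, as expected for a generator whose
effects are strong and clean.

## Numerical choices and degenerate inputs

Duplicate timestamps collapse to their coordinate mean on ingestion.
Traces of < 2 fixes pass filtering unchanged; empty weeks and empty
subsets yield missing features, and weeks with missing values among a
model's selected features are dropped from that model's data. Variance and
PSD floors are 1e-10; the QDA ridge is 1e-6·tr(Σ)/d; K never exceeds the
number of distinct stationary points; mode and argmax ties resolve to the
earliest occurrence; K-means failures at a candidate K (empty clusters)
end the incremental search at the last accepted K. All randomness flows
through explicit integer seeds; derived seeds stay below 2³¹.

## Problem sizes

The test suite exercises the full reference cohort (20 participants × 10
weeks ≈ 1M fixes, ~200 labeled weeks) once, shared across the acceptance
checks: full preprocessing and feature extraction, a 100-iteration LOPO
evaluation, the within-participant comparison, and five 20-iteration
permutation runs. Unit tests run on single constructed weeks (2016 grid
slots) or cohorts of 1–8 participants. The five-feature QDA acceptance
model uses HS, NENT, NC, TD and DMD on the base subset — the five
behavioral channels the generator encodes — fixed a priori rather than
wrapper-selected, so the acceptance run measures the pipeline rather than
the selection search; the wrapper itself is validated separately on small
synthetic tables with known informative features.

## Known limitations

* The labeling rule blends neighboring weeks near mood transitions
  (inherent to interpolation at weekly cadence).
* Week-local clustering makes NC sensitive to week boundaries for places
  visited rarely.
* The optimized-exclusion α is tuned by resubstitution accuracy within
  training folds; a nested CV would be cleaner and costlier.
* DM's documented insensitivity to direction (see above) means DM and DMD
  carry largely redundant information for radial travel; DMN is the
  direction-sensitive member of the family.
* The equirectangular frame distorts near the poles and for >100 km
  excursions; participants commuting between cities stretch its adequacy.
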