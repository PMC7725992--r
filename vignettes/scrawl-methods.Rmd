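---
title: "Handwriting kinematics, feature engineering and the screening benchmark"
author: "scrawl authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handwriting kinematics, feature engineering and the screening benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrawl)
```

## The measurement model

A digitizer tablet samples the pen at a fixed rate (100 Hz in our simulator;
real devices vary, so no operation assumes a rate) and records, per sample:
x/y position in device units (y increasing upward), a timestamp in integer
milliseconds, a binary surface-contact flag, and three contact channels —
pressure, azimuth (rotation about the vertical axis) and altitude (elevation
above the writing plane). The contact channels are physically meaningful only
while the tip touches the paper; rows recorded in air may carry stale device
values, and `scrawl` never uses them for in-air features.

A **segment** is a maximal run of samples in one contact state. We
deliberately avoid the word *stroke*, which in handwriting research usually
denotes a ballistic submovement; segmentation here is purely by the contact
flag. A **pen lift** is an on-surface→in-air transition, so a recording that
starts and ends on paper has `lifts = on-surface segments − 1`, an identity
the tests exploit.

## Kinematic derivation choices

Derivatives are first-order forward differences on the actual timestamps,
`(v[i+1] − v[i]) / (t[i+1] − t[i])`, which keeps them correct under uneven
sampling; timestamps are milliseconds, outputs are per second. No smoothing
is applied by default; `kinematicsOptions(smoothingWindow = k)` exposes a
centred moving average on x and y for noisy devices. Derivative chains are
computed strictly inside segments — a velocity sample never mixes positions
from the two sides of a pen lift, so a segment of *n* samples contributes
*n−1* velocity, *n−2* acceleration and *n−3* jerk samples.

Two conventions needed fixing where common usage is ambiguous:

- **Acceleration is the derivative of speed** (the scalar ‖v‖), describing
  change of speed per time, not the norm of the component-acceleration
  vector. Component accelerations and jerks are successive derivatives of
  the *signed* component velocities.
- **Vertical/horizontal velocity summaries use magnitudes** (overall change
  of vertical/horizontal position per time). Whether signed or absolute
  component velocities are summarized is a genuine degree of freedom;
  `kinematicsOptions(componentSummary = "signed")` switches it, the default
  is magnitude.

Statistical summaries are the seven numbers mean, median, standard
deviation, max, min, and the 5th/95th percentiles — the percentiles because
the extremes are easily distorted by single spikes. Two numerical
conventions are fixed for reproducibility and documented here prominently:
**population standard deviation** (divide by *n*) everywhere, and
**percentiles by linear interpolation between order statistics** (R's
`quantile` type 7). Local extrema of a signal are interior sign changes of
the slope after collapsing equal-value plateaus, so a flat-topped peak
counts once.

## The feature registry

Per task and movement type the registry is: 12 signal vectors × 7 statistics
(84) + 6 segment measures × 5 statistics (30) + 19 scalars = **133**
on-surface. The twelve signals include vertical and horizontal acceleration;
the six segment measures are duration, path length, vertical and horizontal
path length (summed |Δy|, |Δx| — distinct from height/width, which are
coordinate extents; both families are kept because they measure different
things and are both informative). The 19 scalars are pen lifts, the two
extrema counts, four totals, and the twelve row-inclination features. In-air
vectors drop the 21 pressure/altitude/azimuth summaries, leaving **112**;
the in-air scalar mirror of "pen lifts" counts in-air→on-surface returns.
A complete session merges the eight on-surface vectors plus the sentence
in-air vector, task-major: 8 × 133 + 112 = **1176** columns, named
`<task>.<movement>.<feature>` for auditable indexing.

The inclination features capture row drift — writers who do not keep their
writing at a constant height: per-segment y-position statistics (min,
median, mean, max) enter (a) signed first-minus-last segment differences,
(b) signed second-minus-penultimate differences, (c) population variances
across all segments. Sign convention is first-minus-last, so a descending
row gives positive differences. Degenerate inputs follow fixed fallback
rules rather than producing missing values (classifiers downstream need
finite matrices): with < 2 segments all twelve are 0; with < 4 segments the
pre-end differences are 0; signals that cannot be computed (e.g. jerk with
no 4-sample segment) yield zero summaries. Every fallback is reported in
the `FeatureVector`'s degeneracy flags.

## Standardization and the evaluation protocol

Features are z-scored per feature to zero mean and unit variance, with the
population SD, and zero-variance features mapped to 0. Inside
cross-validation the standardizer is **fitted on the training folds only**
and applied unchanged to the held-out fold: fitting on all data would leak
test-set location/scale into training. The protocol is stratified 10-fold
cross-validation repeated 10 times; within a repeat the fold predictions
are pooled into a single confusion matrix before computing the metrics —
per-fold sensitivity/specificity on ~12-subject folds are too unstable to
average meaningfully — and the result reports mean ± SD across the 10
repeats.

Classifiers: random forest (`randomForest`), RBF SVM (`e1071`), and an
AdaBoost stump ensemble implemented in the package (discrete two-class
AdaBoost with depth-1 stumps; each round searches all features and
thresholds exhaustively via cumulative sums over presorted feature orders).
Defaults are the tuned operating points — AdaBoost 340 estimators, random
forest 60 trees / min split 4 / 5 features per split, SVM C = 4, γ = 2⁻⁹ —
and `gridSearch()` exposes the full candidate grids (25, 500 and 100
points). One mapping caveat: the forest's "minimum samples to split" is
implemented through `randomForest`'s `nodesize` (minimum terminal-node
size), the closest control that library exposes; at these magnitudes the
two behave near-identically. The AdaBoost base-stump depth is 1. Grid
search, when used, should be run on training data only (it accepts the CV
protocol arguments); the default benchmark uses the fixed operating points,
which keeps it cheap and deterministic.

## What the simulator emulates — and what it does not

`generateCohort()` produces complete eight-task sessions. Strokes follow a
minimum-jerk polynomial (bell-shaped speed profile) with a perpendicular
arc for letter-like curvature; tremor is additive band-limited noise (4–10
Hz components) windowed to vanish at stroke endpoints; in-air transits
connect strokes; pressure/azimuth/altitude wander smoothly around
device-typical values. Task differences are carried by stroke-count ranges
(1–2 for single letters up to 16–22 for the sentence) and a 1.6× speed
factor for the fast variants. Sampling is 100 Hz by default (configurable).

The dysgraphia effect profile targets exactly the feature families with the
highest reported discriminative value: extra pen lifts (Poisson, +3/task at
full strength), baseline drift of the writing row (SD equal to the 100-unit
letter height at full strength, on top of a 5-unit natural jitter),
doubled tremor amplitude, a −120-unit pressure offset, and 20% slower
strokes. `dysgraphiaProfile(strength)` interpolates linearly toward the
null profile, giving the graded weak/medium/strong conditions used in the
calibration checks. The demographics (120 subjects, 57 affected, 2:1
male:female, 16/120 left-handed, ages 8–15) mirror a realistic school
cohort.

What passing tests on synthetic data do show: the feature pipeline measures
what it claims (every planted effect is recovered through the intended
feature family), the protocol is leakage-free (null cohorts score at
chance), and effect size maps monotonically to accuracy. What they do not
show: performance on real children's handwriting. Real letterforms,
orthography-specific shapes, age-dependent maturation, device quantization
and the subtle, overlapping effect sizes of clinical dysgraphia are all
outside the generator; with the full planted effect the synthetic groups
are far more separable (accuracy saturates near 100%) than clinical groups,
where reported accuracies are closer to 80%. The simulator is a test
harness and calibration instrument, not a substitute cohort.

## Problem sizes and determinism

The calibration checks run four 120-subject cohorts (null, weak, medium,
strong) through generation, extraction of the 1176-feature matrix and the
full 10×10 CV with the fixed random-forest operating point — about 45 s per
cohort on one core, with AdaBoost adding seconds. These sizes were chosen
to match the study-scale cohort exactly while keeping a full verification
run a coffee-break affair. Every stochastic step (simulation, fold
assignment, forest) derives from explicit integer seeds, so cohorts are
byte-identical across runs and `CVResult`s reproduce bit-for-bit.

## Known limitations

- The SVC dialect assumes one sample per line with seven numeric fields;
  vendor formats with extra columns need a column-mapping dialect.
- Duplicate timestamps are rejected rather than merged (differentiation
  needs strictly increasing time); devices that emit them need upstream
  cleaning.
- `nodesize` vs minimum-split mapping, above.
- The AdaBoost implementation is binary-only, which is all this problem
  needs.
- In-air mirror scalars (returns, in-air totals) are a fixed convention;
  only the 112-count is externally constrained, not each member's exact
  in-air definition.
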