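# scrawl

Online handwriting kinematics and dysgraphia screening in R.

Developmental dysgraphia — a disorder of written expression — leaves
measurable traces in *how* a child writes, not just in what the writing looks
like: more pen lifts, a wandering row baseline, denser velocity reversals,
altered pen pressure. Digitizer tablets capture these dynamics as per-sample
streams of position, timestamp, surface-contact flag, pen azimuth/altitude
and tip pressure. `scrawl` turns such recordings into the feature vectors and
classification benchmarks used in dysgraphia screening studies, and ships a
synthetic cohort generator so the entire pipeline can be exercised,
calibrated and tested without access to clinical data.

The package is aimed at researchers in digital biomarkers and handwriting
analysis who need a reproducible reference implementation of the
feature-engineering and evaluation protocol.

## What it computes

For each handwriting task (the eight-task template: letter *l* normal/fast,
syllable *le* normal/fast, *leto*, *lamoken*, *hračkárstvo*, a sentence):

- **Kinematic signal summaries (12 × 7 = 84).** Velocity
  v(t) = ‖(Δx/Δt, Δy/Δt)‖, its vertical/horizontal components, acceleration
  a = dv/dt, jerk j = da/dt, component accelerations/jerks, plus pressure,
  altitude, azimuth — each summarized by mean, median, population SD, max,
  min, and the 5th/95th percentiles. Derivatives are forward differences on
  actual timestamps and never cross a pen lift.
- **Segment geometry summaries (6 × 5 = 30).** A *segment* is a maximal run
  of constant contact state. Duration, path length, vertical/horizontal
  length (summed |Δ| steps), width and height, each summarized across
  segments by mean, median, SD, max, min.
- **Scalars (19).** Pen lifts, counts of velocity/acceleration local extrema,
  total duration/length/vertical/horizontal length, and twelve
  row-inclination features: signed first-vs-last and second-vs-penultimate
  segment differences, and cross-segment variances, of the per-segment
  y-position min/median/mean/max.

That is **133 features per task on-surface**, **112 in-air** (pressure and
tilt are not recorded in air), and a merged per-subject vector of
**8 × 133 + 112 = 1176 features**.

Classification performance is estimated with **stratified 10-fold
cross-validation repeated 10 times** (standardizer fitted on training folds
only), reporting, with dysgraphia as positive class,

    accuracy    = (TP + TN) / (TP + TN + FP + FN) · 100%
    specificity =  TN / (TN + FP) · 100%
    sensitivity =  TP / (TP + FN) · 100%

for AdaBoost (decision-stump ensemble, 340 estimators), random forest
(60 trees, min split 4, 5 features/split) and RBF SVM (C = 4, γ = 2⁻⁹), with
the full hyperparameter grids (25 / 500 / 100 candidates) available for
re-tuning.

## Worked example

```r
library(scrawl)

# simulate a labelled cohort: 120 subjects, 57 with dysgraphia effects
cohort <- generateCohort(presetConfig("table1", seed = 1))
table(cohort$labels)
#>    control dysgraphia
#>         63         57

# one subject, one task
rec <- sessionRecording(cohort$sessions[[1]], "leto")
rec
#> TaskRecording 'leto': 247 samples, 2.46 s, 198 on-surface / 49 in-air

fv <- extractTaskFeatures(rec, "on_surface")
length(fv)                       # 133
featureValues(fv)[c("pen_lifts", "velocity_mean", "pressure_min")]
#>     pen_lifts velocity_mean  pressure_min
#>        4.0000      433.6128      533.0000

# merged feature matrix (SummarizedExperiment, 1176 x 120) and the benchmark
m <- featureMatrix(cohort$sessions, tasks = "all")
dim(m)
#> [1] 1176  120
res <- repeatedStratifiedCV(m, defaultClassifiers()$rf,
                            folds = 10, repeats = 10, seed = 1)
res
#> CVResult: rf, 10-fold x 10 repeats (seed 1)
#>   accuracy    100.0 +/- 0.0 %
#>   specificity 100.0 +/- 0.0 %
#>   sensitivity 100.0 +/- 0.0 %
```

With the full planted effect the groups are linearly separated by several
feature families (pen lifts above all), so cross-validated accuracy
saturates; with the null profile (`presetConfig("null")`) the same pipeline
hovers at chance (~50%), confirming the protocol leaks no label information.

A shell entry point over the same functions is installed at
`inst/scripts/scrawl-cli.R` (`simulate`, `extract`, `evaluate`, `run`
subcommands).

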