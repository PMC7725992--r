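#' @import methods
#' @importFrom stats median quantile rnorm runif rpois sd var predict
#' @importFrom utils read.table write.table head tail
NULL

SAMPLE_COLUMNS <- c("t", "x", "y", "on_surface", "azimuth", "altitude", "pressure")

#' Task identifiers of the handwriting template
#'
#' The eight tasks of the acquisition template, in canonical order: the letter
#' "l" at normal and fast speed, the syllable "le" at normal and fast speed,
#' the word "leto", the pseudoword "lamoken", the difficult word
#' "hrackarstvo", and a full sentence.
#'
#' @return Character vector of the eight task identifiers.
#' @export
#' @examples
#' taskTemplate()
taskTemplate <- function() {
  c("l", "l_fast", "le", "le_fast", "leto", "lamoken", "hrackarstvo", "sentence")
}

#' TaskRecording: one digitized handwriting task
#'
#' Time-ordered pen samples for a single handwriting task. Each sample carries
#' timestamp `t` (milliseconds), position `x`/`y` (device units, y up),
#' surface-contact flag `on_surface` (1 = pen tip on paper), and the pen
#' orientation/pressure channels `azimuth`, `altitude`, `pressure` (device
#' units). Pressure, azimuth and altitude are captured by the device only
#' while the tip touches the surface; in-air rows may hold stale values and
#' are never used for in-air feature computation.
#'
#' Class validity checks structural soundness (columns, types); semantic
#' checks such as strictly increasing timestamps are performed by
#' [validateRecording()] so that defective files can still be inspected.
#'
#' @slot taskId character(1), one of [taskTemplate()] (other ids allowed for
#'   ad-hoc recordings).
#' @slot samples data.frame with columns `t, x, y, on_surface, azimuth,
#'   altitude, pressure`.
#' @export
setClass("TaskRecording",
  representation(taskId = "character", samples = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@taskId) != 1L || is.na(object@taskId) || !nzchar(object@taskId))
      msg <- c(msg, "taskId must be a single non-empty string")
    if (!identical(colnames(object@samples), SAMPLE_COLUMNS))
      msg <- c(msg, sprintf("samples must have columns: %s",
                            paste(SAMPLE_COLUMNS, collapse = ", ")))
    else if (!all(vapply(object@samples, is.numeric, logical(1))))
      msg <- c(msg, "all sample columns must be numeric")
    if (length(msg)) msg else TRUE
  })

#' Construct a TaskRecording
#'
#' @param taskId task identifier (see [taskTemplate()]).
#' @param samples data.frame of pen samples with columns
#'   `t, x, y, on_surface, azimuth, altitude, pressure`.
#' @param check if `TRUE` (default), reject recordings that fail
#'   [validateRecording()]; set to `FALSE` to build a defective recording for
#'   inspection.
#' @return A [TaskRecording-class] object.
#' @export
#' @examples
#' rec <- TaskRecording("l", data.frame(
#'   t = c(0, 10, 20), x = c(0, 1, 2), y = c(0, 0, 0),
#'   on_surface = 1, azimuth = 1500, altitude = 600, pressure = 500))
#' rec
TaskRecording <- function(taskId, samples, check = TRUE) {
  samples <- as.data.frame(samples)[, SAMPLE_COLUMNS]
  samples[] <- lapply(samples, as.numeric)   # canonical double storage
  rownames(samples) <- NULL
  rec <- new("TaskRecording", taskId = as.character(taskId), samples = samples)
  if (check) {
    report <- validateRecording(rec)
    if (nrow(report))
      stop("invalid recording '", taskId, "': ",
           paste(report$message, collapse = "; "), call. = FALSE)
  }
  rec
}

#' @describeIn TaskRecording-class number of pen samples.
#' @param x,object a `TaskRecording`.
#' @export
setMethod("length", "TaskRecording", function(x) nrow(x@samples))

#' Accessors for TaskRecording
#'
#' `penSamples()` returns the sample data.frame; `taskId()` the task
#' identifier.
#'
#' @param x a [TaskRecording-class].
#' @return `penSamples()`: data.frame; `taskId()`: character(1).
#' @export
penSamples <- function(x) {
  stopifnot(is(x, "TaskRecording"))
  x@samples
}

#' @rdname penSamples
#' @export
taskId <- function(x) {
  stopifnot(is(x, "TaskRecording"))
  x@taskId
}

setMethod("show", "TaskRecording", function(object) {
  s <- object@samples
  cat(sprintf("TaskRecording '%s': %d samples, %.2f s, %d on-surface / %d in-air\n",
              object@taskId, nrow(s),
              if (nrow(s)) (s$t[nrow(s)] - s$t[1]) / 1000 else 0,
              sum(s$on_surface == 1), sum(s$on_surface != 1)))
})

#' Session: all template recordings of one subject
#'
#' A labelled collection of [TaskRecording-class] objects for one subject,
#' with the demographics recorded during acquisition.
#'
#' @slot subjectId character(1) opaque identifier.
#' @slot age integer(1) years.
#' @slot sex character(1), "M" or "F".
#' @slot handedness character(1), "L" or "R".
#' @slot label character(1), "dysgraphia", "control" or "unknown".
#' @slot recordings named list of `TaskRecording`, names = task ids.
#' @export
setClass("Session",
  representation(subjectId = "character", age = "integer", sex = "character",
                 handedness = "character", label = "character",
                 recordings = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@label %in% c("dysgraphia", "control", "unknown"))
      msg <- c(msg, "label must be 'dysgraphia', 'control' or 'unknown'")
    if (!object@sex %in% c("M", "F")) msg <- c(msg, "sex must be 'M' or 'F'")
    if (!object@handedness %in% c("L", "R"))
      msg <- c(msg, "handedness must be 'L' or 'R'")
    ids <- names(object@recordings)
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate task ids in recordings")
    ok <- vapply(object@recordings, is, logical(1), class2 = "TaskRecording")
    if (!all(ok)) msg <- c(msg, "recordings must all be TaskRecording objects")
    if (length(msg)) msg else TRUE
  })

setMethod("$", "Session", function(x, name) slot(x, name))

#' Construct a Session
#'
#' @param subjectId opaque subject identifier.
#' @param recordings named list of [TaskRecording-class] (names = task ids);
#'   unnamed lists are named from each recording's own task id.
#' @param age age in years.
#' @param sex "M" or "F".
#' @param handedness "L" or "R".
#' @param label "dysgraphia", "control" or "unknown".
#' @return A [Session-class] object.
#' @export
Session <- function(subjectId, recordings = list(), age = NA_integer_,
                    sex = "M", handedness = "R", label = "unknown") {
  if (length(recordings) && is.null(names(recordings)))
    names(recordings) <- vapply(recordings, taskId, character(1))
  new("Session", subjectId = as.character(subjectId),
      age = as.integer(age), sex = sex, handedness = handedness,
      label = label, recordings = recordings)
}

#' @describeIn Session-class number of recordings held.
#' @param x,object a `Session`.
#' @export
setMethod("length", "Session", function(x) length(x@recordings))

setMethod("show", "Session", function(object) {
  cat(sprintf("Session '%s' (%s, age %s, %s-handed, label: %s): %d task(s)\n",
              object@subjectId, object@sex, object@age, object@handedness,
              object@label, length(object@recordings)))
  if (length(object@recordings))
    cat(" tasks:", paste(names(object@recordings), collapse = ", "), "\n")
})

#' Extract a task recording from a session
#'
#' @param session a [Session-class].
#' @param task task identifier.
#' @return The [TaskRecording-class] for that task.
#' @export
sessionRecording <- function(session, task) {
  stopifnot(is(session, "Session"))
  if (!task %in% names(session@recordings))
    stop("session '", session@subjectId, "' has no recording for task '",
         task, "'", call. = FALSE)
  session@recordings[[task]]
}

#' FeatureVector: named feature values for one task or session
#'
#' Ordered feature values keyed by canonical registry names (see
#' [featureRegistry()]), plus the names of features produced by a degenerate
#' fallback rule (for example jerk statistics when no segment has four
#' samples; such features are set to 0 so downstream matrices stay complete).
#'
#' @slot values named numeric vector.
#' @slot degenerate character vector, subset of `names(values)`.
#' @export
setClass("FeatureVector",
  representation(values = "numeric", degenerate = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
      msg <- c(msg, "values must be uniquely named")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (!all(object@degenerate %in% names(object@values)))
      msg <- c(msg, "degenerate flags must name existing features")
    if (length(msg)) msg else TRUE
  })

FeatureVector <- function(values, degenerate = character()) {
  new("FeatureVector", values = values, degenerate = unique(degenerate))
}

#' @describeIn FeatureVector-class number of features.
#' @param x,object a `FeatureVector`.
#' @export
setMethod("length", "FeatureVector", function(x) length(x@values))

#' @describeIn FeatureVector-class feature names in canonical order.
#' @export
setMethod("names", "FeatureVector", function(x) names(x@values))

#' Accessors for FeatureVector
#'
#' `featureValues()` returns the named numeric vector;
#' `degenerateFeatures()` the names filled in by a fallback rule.
#'
#' @param x a [FeatureVector-class].
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureVector"))
  x@values
}

#' @rdname featureValues
#' @export
degenerateFeatures <- function(x) {
  stopifnot(is(x, "FeatureVector"))
  x@degenerate
}

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector: %d features (%d degenerate)\n",
              length(object@values), length(object@degenerate)))
  print(head(object@values, 5))
  if (length(object@values) > 5) cat("...\n")
})

#' StandardizationStats: per-feature z-scoring parameters
#'
#' Column means and population standard deviations fitted on a training
#' feature matrix; zero-variance columns are flagged and map to 0 when the
#' standardizer is applied.
#'
#' @slot featureNames character, column names the stats belong to.
#' @slot means,sds numeric, same length.
#' @slot zeroVariance character, names of flagged constant columns.
#' @export
setClass("StandardizationStats",
  representation(featureNames = "character", means = "numeric",
                 sds = "numeric", zeroVariance = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@featureNames)
    if (length(object@means) != n || length(object@sds) != n)
      msg <- c(msg, "means/sds length must match featureNames")
    if (any(object@sds < 0)) msg <- c(msg, "sds must be non-negative")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "StandardizationStats", function(object) {
  cat(sprintf("StandardizationStats: %d features, %d zero-variance\n",
              length(object@featureNames), length(object@zeroVariance)))
})

#' ConfusionCounts for binary dysgraphia screening
#'
#' Positive class = dysgraphia: TP are dysgraphic subjects detected, TN are
#' control subjects cleared, FP controls flagged, FN dysgraphic subjects
#' missed.
#'
#' @slot TP,TN,FP,FN non-negative integers.
#' @export
setClass("ConfusionCounts",
  representation(TP = "integer", TN = "integer", FP = "integer", FN = "integer"),
  validity = function(object) {
    v <- c(object@TP, object@TN, object@FP, object@FN)
    if (length(v) != 4L || any(is.na(v)) || any(v < 0))
      "TP, TN, FP, FN must be single non-negative integers"
    else TRUE
  })

#' @rdname ConfusionCounts-class
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return A `ConfusionCounts` object.
#' @export
#' @examples
#' confusionCounts(TP = 3, TN = 4, FP = 1, FN = 2)
confusionCounts <- function(TP, TN, FP, FN) {
  new("ConfusionCounts", TP = as.integer(TP), TN = as.integer(TN),
      FP = as.integer(FP), FN = as.integer(FN))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              object@TP, object@TN, object@FP, object@FN,
              object@TP + object@TN + object@FP + object@FN))
})

#' CVResult: repeated stratified cross-validation outcome
#'
#' Per-repeat accuracy/specificity/sensitivity (percent, fold predictions
#' pooled within each repeat) and their mean and standard deviation across
#' repeats, together with the protocol that produced them.
#'
#' @slot perRepeat data.frame with columns `repeat_`, `accuracy`,
#'   `specificity`, `sensitivity`.
#' @slot means,sds named numeric, one entry per metric.
#' @slot protocol list: `folds`, `repeats`, `seed`, `classifier`.
#' @export
setClass("CVResult",
  representation(perRepeat = "data.frame", means = "numeric",
                 sds = "numeric", protocol = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("accuracy", "specificity", "sensitivity")
    if (!all(need %in% colnames(object@perRepeat)))
      msg <- c(msg, "perRepeat must have accuracy/specificity/sensitivity")
    if (!all(need %in% names(object@means)) || !all(need %in% names(object@sds)))
      msg <- c(msg, "means/sds must be named by metric")
    if (any(object@means[need] < 0 | object@means[need] > 100))
      msg <- c(msg, "metric means must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' Accessors for CVResult
#'
#' `cvMetrics()` returns mean and sd per metric as a data.frame,
#' `cvRepeats()` the per-repeat metric table, `cvProtocol()` the protocol
#' descriptor.
#'
#' @param x a [CVResult-class].
#' @export
cvMetrics <- function(x) {
  stopifnot(is(x, "CVResult"))
  data.frame(metric = names(x@means), mean = unname(x@means),
             sd = unname(x@sds[names(x@means)]))
}

#' @rdname cvMetrics
#' @export
cvRepeats <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@perRepeat
}

#' @rdname cvMetrics
#' @export
cvProtocol <- function(x) {
  stopifnot(is(x, "CVResult"))
  x@protocol
}

setMethod("show", "CVResult", function(object) {
  p <- object@protocol
  cat(sprintf("CVResult: %s, %d-fold x %d repeats (seed %s)\n",
              p$classifier %||% "classifier", p$folds, p$repeats,
              format(p$seed)))
  m <- object@means; s <- object@sds
  for (k in c("accuracy", "specificity", "sensitivity"))
    cat(sprintf("  %-11s %5.1f +/- %.1f %%\n", k, m[[k]], s[[k]]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
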