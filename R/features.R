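VECTOR_STATS <- c("mean", "median", "sd", "max", "min", "p05", "p95")
CONTACT_ONLY_SIGNALS <- c("pressure", "altitude", "azimuth")

SCALAR_FEATURES <- c("pen_lifts", "n_velocity_extrema", "n_acceleration_extrema",
                     "total_duration", "total_length", "total_vertical_length",
                     "total_horizontal_length",
                     paste0("diff_end_", c("min", "median", "mean", "max")),
                     paste0("diff_preend_", c("min", "median", "mean", "max")),
                     paste0("var_y_", c("min", "median", "mean", "max")))

#' Canonical feature registry
#'
#' The fixed, ordered list of feature names extracted per task: 12 kinematic
#' signal vectors x 7 statistics (84), 6 segment-geometry measures x 5
#' statistics (30), and 19 scalars (pen lifts, velocity/acceleration extrema
#' counts, total duration and path lengths, and the twelve row-inclination
#' features) — 133 names for on-surface movement. The in-air registry drops
#' the pressure, altitude and azimuth summaries (the device does not record
#' those channels in air), leaving 112 names. The ordering is stable across
#' runs and versions; merged-session columns derive from it.
#'
#' @param movement `"on_surface"` or `"in_air"`.
#' @return Character vector of 133 or 112 unique names.
#' @export
#' @examples
#' length(featureRegistry("on_surface"))   # 133
#' length(featureRegistry("in_air"))       # 112
featureRegistry <- function(movement = c("on_surface", "in_air")) {
  movement <- match.arg(movement)
  signals <- KINEMATIC_SIGNALS
  if (movement == "in_air") signals <- setdiff(signals, CONTACT_ONLY_SIGNALS)
  vecNames <- as.vector(t(outer(signals, VECTOR_STATS, paste, sep = "_")))
  segNames <- as.vector(t(outer(SEGMENT_MEASURES,
                                c("mean", "median", "sd", "max", "min"),
                                function(m, s) paste("seg", m, s, sep = "_"))))
  c(vecNames, segNames, SCALAR_FEATURES)
}

#' Extract the canonical feature vector for one task
#'
#' Computes, for the requested movement type, the seven-number summaries of
#' the twelve kinematic signal vectors, the five-number summaries of the six
#' segment-geometry measures, and the nineteen scalar features — exactly 133
#' named values for on-surface movement and 112 in-air. Signals that cannot
#' be computed (e.g. jerk when no segment holds four samples) fall back to
#' zeros and are flagged as degenerate, so downstream matrices are always
#' complete and finite; a recording without any segment of the requested
#' movement yields an all-zero, fully flagged vector.
#'
#' @param rec a valid [TaskRecording-class].
#' @param movement `"on_surface"` or `"in_air"`.
#' @param opts a [kinematicsOptions()].
#' @return A [FeatureVector-class] whose names equal
#'   `featureRegistry(movement)`.
#' @export
extractTaskFeatures <- function(rec, movement = c("on_surface", "in_air"),
                                opts = kinematicsOptions()) {
  stopifnot(is(rec, "TaskRecording"))
  movement <- match.arg(movement)
  registry <- featureRegistry(movement)
  vals <- stats::setNames(rep(0, length(registry)), registry)
  degenerate <- character()

  segs <- splitSegments(rec)[[movement]]
  if (!length(segs))
    return(FeatureVector(vals, registry))

  # kinematic signal summaries
  usable <- any(vapply(segs, length, integer(1)) >= 2L)
  signals <- setdiff(registry, c(grep("^seg_", registry, value = TRUE),
                                 SCALAR_FEATURES))
  if (usable) {
    bundle <- computeKinematics(rec, movement, opts)
    for (sig in names(bundle)) {
      v <- signalValues(bundle, sig)
      nm <- paste(sig, VECTOR_STATS, sep = "_")
      if (length(v)) {
        vals[nm] <- summarizeVector(v)
      } else degenerate <- c(degenerate, nm)
    }
    vals["n_velocity_extrema"] <-
      sum(vapply(bundle$velocity, countLocalExtrema, integer(1)))
    if (length(signalValues(bundle, "acceleration")))
      vals["n_acceleration_extrema"] <-
        sum(vapply(bundle$acceleration, countLocalExtrema, integer(1)))
    else degenerate <- c(degenerate, "n_acceleration_extrema")
  } else {
    degenerate <- c(degenerate, signals,
                    c("n_velocity_extrema", "n_acceleration_extrema"))
  }

  # segment geometry
  geoms <- do.call(rbind, lapply(segs, segmentGeometry))
  vals[names(summarizeSegments(geoms))] <- summarizeSegments(geoms)
  vals["total_duration"] <- sum(geoms[, "duration"])
  vals["total_length"] <- sum(geoms[, "path_length"])
  vals["total_vertical_length"] <- sum(geoms[, "vertical_length"])
  vals["total_horizontal_length"] <- sum(geoms[, "horizontal_length"])

  vals["pen_lifts"] <- countPenLifts(rec, movement)

  incl <- inclinationFeatures(segs)
  vals[names(incl)] <- incl
  if (length(segs) < 2L)
    degenerate <- c(degenerate, names(incl))
  else if (length(segs) < 4L)
    degenerate <- c(degenerate, grep("^diff_preend_", names(incl), value = TRUE))

  FeatureVector(vals[registry], intersect(degenerate, registry))
}

#' Merge a session's task vectors into one subject vector
#'
#' Concatenates the eight on-surface task vectors (template order) and the
#' sentence in-air vector: 8 x 133 + 112 = 1176 features, task-major with
#' registry order inside each task. Column names are
#' `<task>.<movement>.<feature>`.
#'
#' @param session a [Session-class] holding all eight template tasks.
#' @param opts a [kinematicsOptions()].
#' @return A [FeatureVector-class] of length 1176.
#' @export
mergeSessionFeatures <- function(session, opts = kinematicsOptions()) {
  stopifnot(is(session, "Session"))
  missing <- setdiff(taskTemplate(), names(session$recordings))
  if (length(missing))
    stop("session '", session$subjectId, "' is missing task(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  prefix <- function(task, movement, nms)
    if (length(nms)) paste(task, movement, nms, sep = ".") else character()
  pieces <- lapply(taskTemplate(), function(task) {
    fv <- extractTaskFeatures(sessionRecording(session, task), "on_surface", opts)
    list(vals = stats::setNames(featureValues(fv),
                                prefix(task, "on_surface", names(fv))),
         deg = prefix(task, "on_surface", degenerateFeatures(fv)))
  })
  fvAir <- extractTaskFeatures(sessionRecording(session, "sentence"), "in_air", opts)
  pieces[[length(pieces) + 1L]] <-
    list(vals = stats::setNames(featureValues(fvAir),
                                prefix("sentence", "in_air", names(fvAir))),
         deg = prefix("sentence", "in_air", degenerateFeatures(fvAir)))
  FeatureVector(unlist(lapply(pieces, `[[`, "vals"), use.names = TRUE),
                as.character(unlist(lapply(pieces, `[[`, "deg"))))
}

.sessionColData <- function(sessions) {
  S4Vectors::DataFrame(
    subject_id = vapply(sessions, function(s) s$subjectId, character(1)),
    label = vapply(sessions, function(s) s$label, character(1)),
    age = vapply(sessions, function(s) s$age, integer(1)),
    sex = vapply(sessions, function(s) s$sex, character(1)),
    handedness = vapply(sessions, function(s) s$handedness, character(1)))
}

#' Build a feature matrix for a cohort
#'
#' Extracts features for every session and assembles them into a
#' [SummarizedExperiment::SummarizedExperiment] with features as rows and
#' subjects as columns; demographics and the dysgraphia label live in
#' `colData`, the task/movement/feature decomposition of each row in
#' `rowData`.
#'
#' @param sessions list of [Session-class].
#' @param tasks which feature set to extract: `"all"` (the merged
#'   1176-feature vector), a single task id (its 133 on-surface features),
#'   `"sentence_in_air"` (112), or `"sentence_both"` (sentence on-surface +
#'   in-air, 245).
#' @param opts a [kinematicsOptions()].
#' @return A `SummarizedExperiment` with assay `"features"`.
#' @export
featureMatrix <- function(sessions, tasks = "all", opts = kinematicsOptions()) {
  stopifnot(length(sessions) > 0)
  extract <- function(ses) {
    if (identical(tasks, "all")) {
      mergeSessionFeatures(ses, opts)
    } else if (identical(tasks, "sentence_in_air")) {
      fv <- extractTaskFeatures(sessionRecording(ses, "sentence"), "in_air", opts)
      FeatureVector(stats::setNames(featureValues(fv),
                                    paste("sentence", "in_air", names(fv), sep = ".")))
    } else if (identical(tasks, "sentence_both")) {
      on <- extractTaskFeatures(sessionRecording(ses, "sentence"), "on_surface", opts)
      air <- extractTaskFeatures(sessionRecording(ses, "sentence"), "in_air", opts)
      FeatureVector(c(
        stats::setNames(featureValues(on),
                        paste("sentence", "on_surface", names(on), sep = ".")),
        stats::setNames(featureValues(air),
                        paste("sentence", "in_air", names(air), sep = "."))))
    } else if (tasks %in% taskTemplate()) {
      fv <- extractTaskFeatures(sessionRecording(ses, tasks), "on_surface", opts)
      FeatureVector(stats::setNames(featureValues(fv),
                                    paste(tasks, "on_surface", names(fv), sep = ".")))
    } else stop("unknown task selector '", tasks, "'", call. = FALSE)
  }
  fvs <- lapply(sessions, extract)
  mat <- vapply(fvs, featureValues, numeric(length(fvs[[1]])))
  rn <- names(fvs[[1]])
  dimnames(mat) <- list(rn, vapply(sessions, function(s) s$subjectId, character(1)))
  parts <- strsplit(rn, ".", fixed = TRUE)
  rd <- S4Vectors::DataFrame(
    task = vapply(parts, `[`, character(1), 1L),
    movement = vapply(parts, `[`, character(1), 2L),
    feature = vapply(parts, function(p) paste(p[-(1:2)], collapse = "."),
                     character(1)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd,
    colData = .sessionColData(sessions))
}

#' Fit a per-feature standardizer
#'
#' Column means and population standard deviations of a feature matrix, the
#' parameters needed to z-score every feature to zero mean and unit
#' variance. Constant features are flagged; [applyStandardizer()] maps them
#' to 0.
#'
#' @param m a `SummarizedExperiment` from [featureMatrix()] (features x
#'   subjects), or a plain numeric matrix in the same orientation.
#' @return A [StandardizationStats-class].
#' @export
fitStandardizer <- function(m) {
  mat <- if (is(m, "SummarizedExperiment")) SummarizedExperiment::assay(m) else m
  if (ncol(mat) < 2L)
    stop("degenerate input: need >= 2 subjects to fit a standardizer",
         call. = FALSE)
  mu <- rowMeans(mat)
  sds <- sqrt(rowMeans((mat - mu)^2))
  new("StandardizationStats", featureNames = rownames(mat),
      means = unname(mu), sds = unname(sds),
      zeroVariance = rownames(mat)[sds == 0])
}

#' Apply a fitted standardizer
#'
#' Z-scores each feature with the *fitted* statistics — when the stats come
#' from training folds they are applied unchanged to test subjects, never
#' refitted, so no test information leaks into the transform. Zero-variance
#' features map to 0.
#'
#' @param m feature matrix as in [fitStandardizer()].
#' @param s a [StandardizationStats-class] whose feature names match `m`.
#' @return Object of the same type as `m`, standardized.
#' @export
applyStandardizer <- function(m, s) {
  stopifnot(is(s, "StandardizationStats"))
  isSE <- is(m, "SummarizedExperiment")
  mat <- if (isSE) SummarizedExperiment::assay(m) else m
  if (!identical(rownames(mat), s@featureNames))
    stop("feature names do not match the fitted standardizer", call. = FALSE)
  denom <- ifelse(s@sds == 0, 1, s@sds)
  out <- (mat - s@means) / denom
  out[s@sds == 0, ] <- 0
  if (isSE) {
    SummarizedExperiment::assay(m, "features") <- out
    m
  } else out
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated with subjects as rows: `subject_id`, `label`, then one
#' column per registry feature name.
#'
#' @param m a `SummarizedExperiment` from [featureMatrix()].
#' @param path output file.
#' @return `writeFeatureMatrix()`: invisibly, `path`;
#'   `readFeatureMatrix()`: a `SummarizedExperiment`.
#' @export
writeFeatureMatrix <- function(m, path) {
  stopifnot(is(m, "SummarizedExperiment"))
  df <- data.frame(subject_id = m$subject_id, label = m$label,
                   t(SummarizedExperiment::assay(m)), check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("subject_id", "label")
  if (!all(meta %in% colnames(df)))
    stop("feature matrix file must have subject_id and label columns",
         call. = FALSE)
  mat <- t(as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE]))
  colnames(mat) <- df$subject_id
  parts <- strsplit(rownames(mat), ".", fixed = TRUE)
  rd <- S4Vectors::DataFrame(
    task = vapply(parts, `[`, character(1), 1L),
    movement = vapply(parts, `[`, character(1), 2L),
    feature = vapply(parts, function(p) paste(p[-(1:2)], collapse = "."),
                     character(1)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat), rowData = rd,
    colData = S4Vectors::DataFrame(subject_id = df$subject_id,
                                   label = df$label))
}

#' Report externally supplied feature weights
#'
#' Hook for feature-relevance reports: takes any weight vector keyed by
#' merged-matrix column names (for example from an external feature-selection
#' run) and returns the non-zero entries aligned to the registry, both
#' per-column and aggregated over tasks per base feature name.
#'
#' @param weights named numeric vector; names must be valid
#'   `<task>.<movement>.<feature>` column names.
#' @param topN how many aggregated features to keep (default all).
#' @return List with `perColumn` (data.frame task/movement/feature/weight,
#'   sorted) and `aggregated` (weight summed over tasks per feature).
#' @export
featureWeightReport <- function(weights, topN = Inf) {
  stopifnot(is.numeric(weights), !is.null(names(weights)))
  parts <- strsplit(names(weights), ".", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    stop("weight names must look like <task>.<movement>.<feature>",
         call. = FALSE)
  df <- data.frame(task = vapply(parts, `[`, character(1), 1L),
                   movement = vapply(parts, `[`, character(1), 2L),
                   feature = vapply(parts, function(p)
                     paste(p[-(1:2)], collapse = "."), character(1)),
                   weight = unname(weights))
  df <- df[df$weight != 0, , drop = FALSE]
  df <- df[order(-df$weight), , drop = FALSE]
  agg <- stats::aggregate(weight ~ feature, df, sum)
  agg <- agg[order(-agg$weight), , drop = FALSE]
  if (is.finite(topN)) agg <- head(agg, topN)
  rownames(df) <- rownames(agg) <- NULL
  list(perColumn = df, aggregated = agg)
}
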