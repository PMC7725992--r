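#' Segment: a maximal run of constant contact state
#'
#' Continuous movement between a transition from in-air to on-surface state
#' or vice versa. Distinct from a ballistic "stroke": segmentation is purely
#' by the contact flag.
#'
#' @slot movement "on_surface" or "in_air".
#' @slot samples data.frame of the contiguous pen samples.
#' @slot index 0-based ordinal among segments of the same movement type.
#' @export
setClass("Segment",
  representation(movement = "character", samples = "data.frame",
                 index = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@movement %in% c("on_surface", "in_air"))
      msg <- c(msg, "movement must be 'on_surface' or 'in_air'")
    if (!nrow(object@samples)) msg <- c(msg, "segment must be non-empty")
    st <- unique(object@samples$on_surface)
    if (length(st) > 1L) msg <- c(msg, "segment mixes contact states")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment #%d (%s): %d samples\n", object@index,
              object@movement, nrow(object@samples)))
})

#' @describeIn Segment-class number of samples in the segment.
#' @param x,object a `Segment`.
#' @export
setMethod("length", "Segment", function(x) nrow(x@samples))

#' Split a recording into on-surface and in-air segments
#'
#' Segments partition the samples: every sample belongs to exactly one
#' maximal run of constant contact state, and concatenating the runs in
#' order reproduces the recording. Contact flags other than 1 are treated as
#' in-air.
#'
#' @param rec a [TaskRecording-class].
#' @return List with elements `on_surface` and `in_air`, each a list of
#'   [Segment-class] in temporal order.
#' @export
#' @examples
#' rec <- TaskRecording("l", data.frame(
#'   t = seq(0, 40, 10), x = 0:4, y = 0, on_surface = c(1, 1, 0, 0, 1),
#'   azimuth = 0, altitude = 0, pressure = c(1, 1, 0, 0, 1)))
#' lengths(splitSegments(rec))   # 2 on-surface, 1 in-air
splitSegments <- function(rec) {
  stopifnot(is(rec, "TaskRecording"))
  s <- rec@samples
  state <- as.integer(s$on_surface == 1)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list(on_surface = list(), in_air = list())
  for (i in seq_along(r$values)) {
    mv <- if (r$values[i] == 1L) "on_surface" else "in_air"
    seg <- new("Segment", movement = mv,
               samples = s[starts[i]:ends[i], , drop = FALSE],
               index = length(out[[mv]]))
    out[[mv]][[length(out[[mv]]) + 1L]] <- seg
  }
  out
}

#' Accessors for Segment
#'
#' `segmentSamples()` returns the segment's sample data.frame,
#' `segmentMovement()` its contact state.
#'
#' @param x a [Segment-class].
#' @export
segmentSamples <- function(x) {
  stopifnot(is(x, "Segment"))
  x@samples
}

#' @rdname segmentSamples
#' @export
segmentMovement <- function(x) {
  stopifnot(is(x, "Segment"))
  x@movement
}

#' Count pen lifts
#'
#' A pen lift is a transition from on-surface to in-air contact state. The
#' count depends only on the flag sequence, never on the in-air trajectory.
#' With `movement = "in_air"` the mirrored transitions (in-air to
#' on-surface returns) are counted instead, which is the natural "lift"
#' analogue for in-air feature vectors.
#'
#' @param rec a [TaskRecording-class].
#' @param movement which transition direction to count.
#' @return Integer count.
#' @export
#' @examples
#' rec <- TaskRecording("l", data.frame(
#'   t = seq(0, 30, 10), x = 0, y = 0, on_surface = c(1, 0, 1, 0),
#'   azimuth = 0, altitude = 0, pressure = 0))
#' countPenLifts(rec)   # 2
countPenLifts <- function(rec, movement = c("on_surface", "in_air")) {
  stopifnot(is(rec, "TaskRecording"))
  movement <- match.arg(movement)
  state <- as.integer(rec@samples$on_surface == 1)
  if (length(state) < 2L) return(0L)
  d <- diff(state)
  if (movement == "on_surface") sum(d == -1L) else sum(d == 1L)
}

SEGMENT_MEASURES <- c("duration", "path_length", "vertical_length",
                      "horizontal_length", "width", "height")

#' Geometry of a segment
#'
#' Duration in seconds; `path_length` = summed Euclidean steps;
#' `vertical_length` / `horizontal_length` = summed absolute coordinate
#' steps (the path-length components — distinct from extent); `width` /
#' `height` = coordinate extent max - min. A single-sample segment has zero
#' for every measure. By construction `width <= horizontal_length` and
#' `height <= vertical_length`.
#'
#' @param seg a [Segment-class].
#' @return Named numeric vector of the six measures.
#' @export
segmentGeometry <- function(seg) {
  stopifnot(is(seg, "Segment"))
  s <- seg@samples
  if (nrow(s) < 2L)
    return(c(duration = 0, path_length = 0, vertical_length = 0,
             horizontal_length = 0, width = 0, height = 0))
  dx <- diff(s$x); dy <- diff(s$y)
  c(duration = (s$t[nrow(s)] - s$t[1]) / 1000,
    path_length = sum(sqrt(dx^2 + dy^2)),
    vertical_length = sum(abs(dy)),
    horizontal_length = sum(abs(dx)),
    width = max(s$x) - min(s$x),
    height = max(s$y) - min(s$y))
}

#' Five-number summaries of segment geometry across segments
#'
#' For each of the six geometry measures: mean, median, standard deviation
#' (population form), maximum and minimum across segments — 30 values.
#'
#' @param geoms list of geometry vectors from [segmentGeometry()] (or a
#'   matrix with one row per segment).
#' @return Named numeric vector of length 30, names
#'   `seg_<measure>_<statistic>`.
#' @export
summarizeSegments <- function(geoms) {
  if (is.list(geoms)) geoms <- do.call(rbind, geoms)
  if (is.null(geoms) || !nrow(geoms))
    stop("degenerate input: no segment geometries to summarize", call. = FALSE)
  stats <- c(mean = mean, median = median, sd = .popSd,
             max = max, min = min)
  out <- numeric(0)
  for (m in SEGMENT_MEASURES) {
    v <- geoms[, m]
    s <- vapply(stats, function(f) f(v), numeric(1))
    names(s) <- paste("seg", m, names(stats), sep = "_")
    out <- c(out, s)
  }
  out
}

.popVar <- function(v) mean((v - mean(v))^2)

#' Handwriting-row inclination features
#'
#' Captures the tendency of some writers not to keep handwriting at a
#' constant height but to drift from the row. For the per-segment y-position
#' statistics (min, median, mean, max): `diff_end_*` is the signed first
#' minus last segment difference; `diff_preend_*` the second minus
#' penultimate; `var_y_*` the population variance of the statistic across
#' all segments. With fewer than 2 segments all twelve values are 0; with
#' fewer than 4 segments the pre-end differences are 0 (a fixed fallback so
#' downstream matrices stay complete).
#'
#' @param segments list of [Segment-class] (typically one movement type, in
#'   temporal order).
#' @return Named numeric vector of length 12.
#' @export
inclinationFeatures <- function(segments) {
  if (!length(segments))
    stop("degenerate input: no segments for inclination features",
         call. = FALSE)
  statNames <- c("min", "median", "mean", "max")
  ys <- t(vapply(segments, function(seg) {
    y <- seg@samples$y
    c(min = min(y), median = median(y), mean = mean(y), max = max(y))
  }, numeric(4)))
  n <- nrow(ys)
  diffEnd <- if (n >= 2L) ys[1L, ] - ys[n, ] else stats::setNames(rep(0, 4), statNames)
  diffPre <- if (n >= 4L) ys[2L, ] - ys[n - 1L, ] else stats::setNames(rep(0, 4), statNames)
  varY <- if (n >= 2L) apply(ys, 2, .popVar) else stats::setNames(rep(0, 4), statNames)
  c(stats::setNames(diffEnd, paste0("diff_end_", statNames)),
    stats::setNames(diffPre, paste0("diff_preend_", statNames)),
    stats::setNames(varY, paste0("var_y_", statNames)))
}
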