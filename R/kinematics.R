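#' Finite differences on irregular timestamps
#'
#' First-order forward differences `(v[i+1]-v[i]) / (t[i+1]-t[i])`, with
#' timestamps in milliseconds, so the result is in input units per second.
#' Robust to uneven sampling because actual timestamps are used.
#'
#' @param values numeric vector, length >= 2.
#' @param times timestamps in milliseconds, strictly increasing, same length.
#' @return Numeric vector of length `length(values) - 1`.
#' @export
#' @examples
#' finiteDifference(c(0, 1), c(0, 1000))   # 1 unit/s
finiteDifference <- function(values, times) {
  if (length(values) != length(times))
    stop("values and times must have equal length", call. = FALSE)
  if (length(values) < 2L)
    stop("degenerate input: need at least 2 samples to differentiate",
         call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  diff(values) / (dt / 1000)
}

.movingAverage <- function(v, window) {
  if (window <= 1L || length(v) < window) return(v)
  as.numeric(stats::filter(v, rep(1 / window, window), sides = 2)) ->
    sm
  # keep original values where the centred window falls off the ends
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}

#' Options for kinematic signal derivation
#'
#' @param smoothingWindow moving-average window (samples) applied to x and y
#'   before differencing; 0 or 1 disables smoothing (default 0 — no filter).
#' @param componentSummary whether the vertical/horizontal *velocity*
#'   summaries are taken over magnitudes (`"magnitude"`, default: overall
#'   change of vertical/horizontal position per time) or signed values.
#'   Component accelerations and jerks are always derivatives of the signed
#'   component velocities.
#' @return List of class `kinematicsOptions`.
#' @export
kinematicsOptions <- function(smoothingWindow = 0L,
                              componentSummary = c("magnitude", "signed")) {
  structure(list(smoothingWindow = as.integer(smoothingWindow),
                 componentSummary = match.arg(componentSummary)),
            class = "kinematicsOptions")
}

KINEMATIC_SIGNALS <- c("velocity", "velocity_vertical", "velocity_horizontal",
                       "acceleration", "acceleration_vertical",
                       "acceleration_horizontal",
                       "jerk", "jerk_vertical", "jerk_horizontal",
                       "pressure", "altitude", "azimuth")

# per-segment derivative chain; returns list of per-signal numeric vectors
.segmentKinematics <- function(seg, opts) {
  s <- seg@samples
  n <- nrow(s)
  out <- list()
  if (n >= 2L) {
    x <- .movingAverage(s$x, opts$smoothingWindow)
    y <- .movingAverage(s$y, opts$smoothingWindow)
    t <- s$t
    vx <- finiteDifference(x, t)
    vy <- finiteDifference(y, t)
    speed <- sqrt(vx^2 + vy^2)
    tv <- t[-n]                       # left-endpoint times of the v series
    out$velocity <- speed
    out$velocity_vertical <- if (opts$componentSummary == "magnitude") abs(vy) else vy
    out$velocity_horizontal <- if (opts$componentSummary == "magnitude") abs(vx) else vx
    if (n >= 3L) {
      out$acceleration <- finiteDifference(speed, tv)
      ax <- finiteDifference(vx, tv)
      ay <- finiteDifference(vy, tv)
      out$acceleration_vertical <- ay
      out$acceleration_horizontal <- ax
      if (n >= 4L) {
        ta <- tv[-length(tv)]
        out$jerk <- finiteDifference(out$acceleration, ta)
        out$jerk_vertical <- finiteDifference(ay, ta)
        out$jerk_horizontal <- finiteDifference(ax, ta)
      }
    }
  }
  out
}

#' Derive kinematic signal vectors from a recording
#'
#' Splits the recording into segments of the requested movement type and
#' differentiates strictly within segments, so no derivative ever spans a
#' pen lift: velocity components are forward differences of x and y; speed is
#' their Euclidean norm; acceleration is the derivative of speed (change of
#' speed per time); jerk the derivative of acceleration; component
#' accelerations/jerks are successive derivatives of the signed component
#' velocities. For on-surface movement the raw pressure, altitude and azimuth
#' samples are included; the device does not record them in air, so in-air
#' bundles omit them.
#'
#' @param rec a valid [TaskRecording-class].
#' @param movement `"on_surface"` or `"in_air"`.
#' @param opts a [kinematicsOptions()].
#' @return A list of class `KinematicBundle`: one element per signal, each a
#'   list of per-segment numeric vectors (use [signalValues()] to pool them).
#' @export
computeKinematics <- function(rec, movement = c("on_surface", "in_air"),
                              opts = kinematicsOptions()) {
  movement <- match.arg(movement)
  segs <- splitSegments(rec)[[movement]]
  if (!length(segs) || !any(vapply(segs, length, integer(1)) >= 2L))
    stop("no usable ", movement, " segment with >= 2 samples", call. = FALSE)
  signals <- KINEMATIC_SIGNALS
  if (movement == "in_air")
    signals <- setdiff(signals, c("pressure", "altitude", "azimuth"))
  bundle <- stats::setNames(rep(list(list()), length(signals)), signals)
  for (seg in segs) {
    derived <- .segmentKinematics(seg, opts)
    for (nm in names(derived))
      bundle[[nm]][[length(bundle[[nm]]) + 1L]] <- derived[[nm]]
    if (movement == "on_surface") {
      s <- seg@samples
      bundle$pressure[[length(bundle$pressure) + 1L]] <- s$pressure
      bundle$altitude[[length(bundle$altitude) + 1L]] <- s$altitude
      bundle$azimuth[[length(bundle$azimuth) + 1L]] <- s$azimuth
    }
  }
  structure(bundle, class = "KinematicBundle", movement = movement)
}

#' Pool a signal's per-segment vectors
#'
#' @param bundle a `KinematicBundle` from [computeKinematics()].
#' @param signal signal name, e.g. `"velocity"`.
#' @return Numeric vector of all per-segment values concatenated in order.
#' @export
signalValues <- function(bundle, signal) {
  stopifnot(inherits(bundle, "KinematicBundle"))
  if (!signal %in% names(bundle))
    stop("bundle holds no signal '", signal, "'", call. = FALSE)
  unlist(bundle[[signal]], use.names = FALSE) %||% numeric()
}

.popSd <- function(v) sqrt(mean((v - mean(v))^2))

#' Seven-number summary of a signal vector
#'
#' Mean, median, standard deviation (population form, divide by n), maximum,
#' minimum, and the 5th and 95th percentiles (linear interpolation between
#' order statistics), in that order. The percentiles are reported alongside
#' the extremes because the extremes are easily distorted by abrupt peaks in
#' the signal.
#'
#' @param v non-empty finite numeric vector.
#' @return Named numeric vector `mean, median, sd, max, min, p05, p95`.
#' @export
#' @examples
#' summarizeVector(c(1, 2, 3, 4, 5))
summarizeVector <- function(v) {
  if (!length(v))
    stop("degenerate input: cannot summarize an empty vector", call. = FALSE)
  if (any(!is.finite(v)))
    stop("vector contains non-finite values", call. = FALSE)
  q <- unname(quantile(v, c(0.05, 0.95), type = 7))
  c(mean = mean(v), median = median(v), sd = .popSd(v),
    max = max(v), min = min(v), p05 = q[1], p95 = q[2])
}

#' Count local extrema of a signal
#'
#' Interior points where the slope changes sign. Runs of equal values
#' (plateaus) are collapsed to single points first, so a plateau bounded by
#' opposite-sign slopes counts as one extremum. Monotone and constant
#' signals have none.
#'
#' @param v non-empty numeric vector.
#' @return Integer count.
#' @export
#' @examples
#' countLocalExtrema(c(0, 1, 0, 1, 0))   # 3
countLocalExtrema <- function(v) {
  if (!length(v)) stop("cannot count extrema of an empty vector", call. = FALSE)
  v <- v[c(TRUE, diff(v) != 0)]          # collapse plateaus
  if (length(v) < 3L) return(0L)
  d <- sign(diff(v))
  sum(d[-length(d)] * d[-1L] < 0)
}
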