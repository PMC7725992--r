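# Geometry constants of the simulated template (device units): letter bodies
# are ~100 units tall, strokes advance ~60 units in x, tablet channels use
# WACOM-like ranges.
LETTER_HEIGHT <- 100
STROKE_ADVANCE <- 60
PRESSURE_BASE <- 600
AZIMUTH_BASE <- 1500
ALTITUDE_BASE <- 600

# strokes per task: ranges drawn per subject; fast variants mirror their
# normal counterparts, longer items need more segments, the sentence most
TASK_STROKE_RANGES <- list(
  l = c(1L, 2L), l_fast = c(1L, 2L), le = c(2L, 3L), le_fast = c(2L, 3L),
  leto = c(3L, 5L), lamoken = c(5L, 7L), hrackarstvo = c(8L, 11L),
  sentence = c(16L, 22L))

#' Group-difference profile for the simulator
#'
#' The per-channel effect magnitudes a simulated dysgraphia group receives,
#' aimed at the feature families with the highest reported discriminative
#' weight: extra pen lifts, vertical drift of the writing row (segment-y
#' variance and end-segment differences), denser velocity extrema (tremor),
#' a pressure offset, and a stroke-speed change. The null profile (all
#' deltas 0, gains 1) produces writing indistinguishable from controls.
#'
#' @param penLiftRateDelta expected extra pen lifts per task (Poisson rate,
#'   >= 0).
#' @param baselineDriftSd standard deviation (device units) of the
#'   per-segment drift of the writing-row baseline, added on top of the
#'   natural jitter.
#' @param tremorGain multiplier (>= 1) on tremor amplitude, which raises the
#'   density of velocity extrema.
#' @param pressureShift additive offset on pen pressure (device units).
#' @param speedScale multiplier on stroke velocity (1 = unchanged; < 1
#'   slower).
#' @return List of class `effectProfile`.
#' @export
effectProfile <- function(penLiftRateDelta = 0, baselineDriftSd = 0,
                          tremorGain = 1, pressureShift = 0, speedScale = 1) {
  stopifnot(penLiftRateDelta >= 0, baselineDriftSd >= 0, tremorGain >= 1,
            speedScale > 0)
  structure(list(penLiftRateDelta = penLiftRateDelta,
                 baselineDriftSd = baselineDriftSd, tremorGain = tremorGain,
                 pressureShift = pressureShift, speedScale = speedScale),
            class = "effectProfile")
}

#' @rdname effectProfile
#' @export
nullProfile <- function() effectProfile()

#' @rdname effectProfile
#' @param strength scales the dysgraphia effect: 1 = the full ("strong")
#'   profile of +3 pen lifts per task, baseline drift comparable to the
#'   letter height, doubled tremor amplitude, -120 units of pressure and 20%
#'   slower strokes; intermediate values interpolate towards the null
#'   profile.
#' @export
dysgraphiaProfile <- function(strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  effectProfile(penLiftRateDelta = 3 * strength,
                baselineDriftSd = LETTER_HEIGHT * strength,
                tremorGain = 1 + 1 * strength,
                pressureShift = -120 * strength,
                speedScale = 1 - 0.2 * strength)
}

#' Simulator configuration
#'
#' @param nSubjects cohort size.
#' @param nDysgraphia how many subjects receive the effect profile.
#' @param ageRange integer range of ages (years), drawn uniformly.
#' @param maleRatio,leftHandedRatio demographic draw probabilities.
#' @param samplingRate tablet sampling rate in Hz (default 100).
#' @param effect the [effectProfile()] applied to the dysgraphia group.
#' @param seed integer seed; the generated cohort is a pure function of the
#'   configuration.
#' @return List of class `generatorConfig`.
#' @export
generatorConfig <- function(nSubjects = 120L, nDysgraphia = 57L,
                            ageRange = c(8L, 15L), maleRatio = 80 / 120,
                            leftHandedRatio = 16 / 120, samplingRate = 100,
                            effect = dysgraphiaProfile(), seed = 1L) {
  stopifnot(nDysgraphia >= 0, nDysgraphia <= nSubjects, samplingRate > 0,
            inherits(effect, "effectProfile"))
  structure(list(nSubjects = as.integer(nSubjects),
                 nDysgraphia = as.integer(nDysgraphia),
                 ageRange = as.integer(ageRange), maleRatio = maleRatio,
                 leftHandedRatio = leftHandedRatio,
                 samplingRate = samplingRate, effect = effect,
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

#' @rdname generatorConfig
#' @param preset `"table1"` — the study-sized cohort (120 subjects, 57
#'   dysgraphia / 63 control) with the full effect profile; `"null"` — same
#'   cohort with the null profile (no group difference); `"strong"` — alias
#'   of `"table1"`.
#' @export
presetConfig <- function(preset = c("table1", "null", "strong"), seed = 1L) {
  preset <- match.arg(preset)
  effect <- switch(preset, null = nullProfile(), dysgraphiaProfile(1))
  generatorConfig(effect = effect, seed = seed)
}

#' Simulate one pen stroke
#'
#' A smooth on-surface trajectory from `start` to `target` with a
#' minimum-jerk (bell-shaped speed) profile, plus a perpendicular arc so the
#' path curves like a letter body. Tremor is additive band-limited noise
#' (a few random 4-10 Hz components) whose amplitude scales with
#' `tremorAmp * tremorGain`; it is windowed to vanish at the endpoints, so
#' the stroke always ends exactly on `target`. Pressure is the base level
#' plus the profile shift plus smooth noise; azimuth/altitude wander slowly
#' around device-typical values. Consumes the ambient RNG stream.
#'
#' @param start,target numeric `c(x, y)` endpoints.
#' @param duration stroke duration in seconds (> 0).
#' @param profile an [effectProfile()].
#' @param samplingRate Hz.
#' @param tremorAmp base tremor amplitude in device units (0 = noise-free).
#' @param pressureNoiseSd pressure noise magnitude (0 = noise-free).
#' @param arcHeight height of the perpendicular arc (device units).
#' @param t0 timestamp of the first sample (ms).
#' @return data.frame of on-surface pen samples.
#' @export
generateStroke <- function(start, target, duration, profile = nullProfile(),
                           samplingRate = 100, tremorAmp = 1.2,
                           pressureNoiseSd = 15, arcHeight = 25, t0 = 0) {
  if (duration <= 0) stop("stroke duration must be positive", call. = FALSE)
  n <- max(2L, as.integer(round(duration * samplingRate)) + 1L)
  tau <- seq(0, 1, length.out = n)
  sProf <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5      # minimum-jerk position
  dx <- target[1] - start[1]; dy <- target[2] - start[2]
  len <- sqrt(dx^2 + dy^2)
  # unit perpendicular for the arc (zero vector if endpoints coincide)
  perp <- if (len > 0) c(-dy, dx) / len else c(0, 0)
  arc <- arcHeight * sin(pi * tau)
  x <- start[1] + dx * sProf + perp[1] * arc
  y <- start[2] + dy * sProf + perp[2] * arc

  amp <- tremorAmp * profile$tremorGain
  if (amp > 0) {
    tt <- tau * duration
    tremor <- function() {
      f <- runif(3, 4, 10); ph <- runif(3, 0, 2 * pi)
      a <- amp * runif(3, 0.5, 1)
      rowSums(sapply(seq_len(3), function(k) a[k] * sin(2 * pi * f[k] * tt + ph[k])))
    }
    env <- sin(pi * tau)                            # endpoints stay exact
    x <- x + env * tremor()
    y <- y + env * tremor()
  }

  press <- PRESSURE_BASE + profile$pressureShift
  if (pressureNoiseSd > 0)
    press <- press + as.numeric(.movingAverage(rnorm(n, 0, pressureNoiseSd * 2), 5L))
  press <- round(pmax(press, 1))
  az <- round(AZIMUTH_BASE + .movingAverage(rnorm(n, 0, 40), 7L))
  al <- round(ALTITUDE_BASE + .movingAverage(rnorm(n, 0, 20), 7L))
  dt <- 1000 / samplingRate
  data.frame(t = t0 + round(dt * (seq_len(n) - 1L)), x = x, y = y,
             on_surface = 1, azimuth = az, altitude = al,
             pressure = rep(press, length.out = n))
}

.inAirTransit <- function(from, to, duration, samplingRate, t0, azimuth,
                          altitude) {
  n <- max(2L, as.integer(round(duration * samplingRate)))
  tau <- seq(0, 1, length.out = n + 1L)[-1L]        # exclude the lift point
  sProf <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  dt <- 1000 / samplingRate
  data.frame(t = t0 + round(dt * seq_len(n)),
             x = from[1] + (to[1] - from[1]) * sProf,
             y = from[2] + (to[2] - from[2]) * sProf,
             on_surface = 0, azimuth = azimuth, altitude = altitude,
             pressure = 0)
}

#' Simulate one handwriting task
#'
#' Draws the task's stroke count (plus Poisson extra pen lifts under the
#' effect profile), lays the strokes left to right along a writing row whose
#' baseline jitters naturally and additionally drifts by
#' `baselineDriftSd`, and connects them with in-air transits. Fast task
#' variants ("l_fast", "le_fast") are written at higher speed; the profile's
#' `speedScale` multiplies stroke velocity on top. The recording starts and
#' ends on-surface, so its pen-lift count equals stroke count - 1.
#'
#' @param task task id from [taskTemplate()].
#' @param profile an [effectProfile()].
#' @param samplingRate Hz.
#' @param tremorAmp,pressureNoiseSd base noise magnitudes, see
#'   [generateStroke()].
#' @return A valid [TaskRecording-class].
#' @export
generateTask <- function(task, profile = nullProfile(), samplingRate = 100,
                         tremorAmp = 1.2, pressureNoiseSd = 15) {
  if (!task %in% taskTemplate())
    stop("unknown task '", task, "'", call. = FALSE)
  rng <- TASK_STROKE_RANGES[[task]]
  nStrokes <- sample(rng[1]:rng[2], 1L) + rpois(1L, profile$penLiftRateDelta)
  fast <- grepl("_fast$", task)
  speed <- profile$speedScale * (if (fast) 1.6 else 1)
  jitterSd <- sqrt(5^2 + profile$baselineDriftSd^2)

  pieces <- list()
  t0 <- 0
  pos <- c(0, 0)
  for (k in seq_len(nStrokes)) {
    targetX <- pos[1] + STROKE_ADVANCE * runif(1, 0.7, 1.3)
    targetY <- rnorm(1, 0, jitterSd)
    up <- runif(1) < 0.5   # alternate letter bodies up/down a little
    arch <- LETTER_HEIGHT * runif(1, 0.6, 1.2) * (if (up) 1 else -0.4)
    dur <- runif(1, 0.25, 0.45) / speed
    stroke <- generateStroke(pos, c(targetX, targetY), dur, profile,
                             samplingRate, tremorAmp, pressureNoiseSd,
                             arcHeight = arch, t0 = t0)
    pieces[[length(pieces) + 1L]] <- stroke
    pos <- c(targetX, targetY)
    t0 <- stroke$t[nrow(stroke)]
    if (k < nStrokes) {
      nextStart <- c(pos[1] + STROKE_ADVANCE * runif(1, 0.2, 0.6),
                     rnorm(1, 0, jitterSd))
      air <- .inAirTransit(pos, nextStart, runif(1, 0.08, 0.2) / speed,
                           samplingRate, t0,
                           azimuth = stroke$azimuth[nrow(stroke)],
                           altitude = stroke$altitude[nrow(stroke)])
      pieces[[length(pieces) + 1L]] <- air
      pos <- nextStart
      t0 <- air$t[nrow(air)]
    }
  }
  samples <- do.call(rbind, pieces)
  # joined pieces share their boundary timestamp; drop the duplicated rows
  keep <- c(TRUE, diff(samples$t) > 0)
  TaskRecording(task, samples[keep, , drop = FALSE])
}

#' Simulate a labelled handwriting cohort
#'
#' Generates `nSubjects` complete eight-task sessions; the first
#' `nDysgraphia` subjects (in a seed-determined shuffled order) receive the
#' configured effect profile, the rest the null profile. Demographics are
#' drawn from the configured ratios. Byte-identical output for identical
#' configurations.
#'
#' @param config a [generatorConfig()].
#' @return List with `sessions` (list of [Session-class]) and `labels`
#'   (factor, levels control/dysgraphia).
#' @export
#' @examples
#' cohort <- generateCohort(generatorConfig(nSubjects = 4, nDysgraphia = 2))
#' table(cohort$labels)
generateCohort <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  n <- config$nSubjects
  labels <- sample(rep(c("dysgraphia", "control"),
                       c(config$nDysgraphia, n - config$nDysgraphia)))
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    profile <- if (labels[i] == "dysgraphia") config$effect else nullProfile()
    recs <- lapply(taskTemplate(), generateTask, profile = profile,
                   samplingRate = config$samplingRate)
    names(recs) <- taskTemplate()
    sessions[[i]] <- Session(
      subjectId = sprintf("S%03d", i), recordings = recs,
      age = sample(config$ageRange[1]:config$ageRange[2], 1L),
      sex = if (runif(1) < config$maleRatio) "M" else "F",
      handedness = if (runif(1) < config$leftHandedRatio) "L" else "R",
      label = labels[i])
  }
  list(sessions = sessions,
       labels = factor(labels, levels = c("control", "dysgraphia")))
}
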