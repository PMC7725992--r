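# Independent brute-force oracles and fixture builders. The oracles never
# call the package functions they are used to check.

# seven-number summary, computed from first principles
bruteSummary <- function(v) {
  n <- length(v)
  vs <- sort(v)
  m <- sum(v) / n
  med <- if (n %% 2 == 1) vs[(n + 1) / 2] else (vs[n / 2] + vs[n / 2 + 1]) / 2
  psd <- sqrt(sum((v - m)^2) / n)
  pct <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    if (lo + 1 >= n) vs[n] else vs[lo + 1] + (h - lo) * (vs[lo + 2] - vs[lo + 1])
  }
  c(mean = m, median = med, sd = psd, max = vs[n], min = vs[1],
    p05 = pct(0.05), p95 = pct(0.95))
}

# five-number summary used for segment measures
bruteFive <- function(v) {
  s7 <- bruteSummary(v)
  s7[c("mean", "median", "sd", "max", "min")]
}

# brute-force run-length encoder over a binary flag sequence
bruteRuns <- function(flags) {
  runs <- list()
  start <- 1L
  for (i in seq_along(flags)) {
    if (i == length(flags) || flags[i + 1] != flags[i]) {
      runs[[length(runs) + 1L]] <- list(value = flags[start],
                                        start = start, end = i)
      start <- i + 1L
    }
  }
  runs
}

# brute-force local-extrema count: collapse plateaus, then scan triples
bruteExtrema <- function(v) {
  w <- v[1]
  for (i in seq_along(v)[-1]) if (v[i] != w[length(w)]) w <- c(w, v[i])
  count <- 0L
  if (length(w) >= 3)
    for (i in 2:(length(w) - 1))
      if ((w[i] - w[i - 1]) * (w[i + 1] - w[i]) < 0) count <- count + 1L
  count
}

# recording fixture with full control over channels
makeRecording <- function(t, x, y, flags, azimuth = 1500, altitude = 600,
                          pressure = NULL, task = "l", check = TRUE) {
  n <- length(t)
  if (is.null(pressure)) pressure <- ifelse(flags == 1, 500, 0)
  TaskRecording(task, data.frame(
    t = t, x = rep_len(x, n), y = rep_len(y, n),
    on_surface = rep_len(flags, n), azimuth = rep_len(azimuth, n),
    altitude = rep_len(altitude, n), pressure = rep_len(pressure, n)),
    check = check)
}

# random recording with integer fields (for bit-exact round-trip checks)
randomIntRecording <- function(n = 20, task = "l") {
  flags <- sample(c(0L, 1L), n, replace = TRUE)
  if (!any(flags == 1)) flags[sample(n, 1)] <- 1L
  makeRecording(
    t = cumsum(sample(1:20, n, replace = TRUE)),
    x = sample(-500:500, n, replace = TRUE),
    y = sample(-500:500, n, replace = TRUE),
    flags = flags,
    azimuth = sample(0:3599, n, replace = TRUE),
    altitude = sample(0:900, n, replace = TRUE),
    pressure = ifelse(flags == 1, sample(1:1023, n, replace = TRUE), 0))
}

# small fully-labelled cohort for evaluation tests
tinyCohort <- function(n = 8, nDys = 4, seed = 11, strength = 1) {
  generateCohort(generatorConfig(nSubjects = n, nDysgraphia = nDys,
                                 effect = dysgraphiaProfile(strength),
                                 seed = seed))
}
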