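test_that("segments partition the recording and match a brute-force RLE", {
  rec1 <- makeRecording(t = c(0, 10, 20), x = 0, y = 0, flags = 1)
  segs1 <- splitSegments(rec1)
  expect_length(segs1$on_surface, 1L)
  expect_length(segs1$in_air, 0L)

  rec2 <- makeRecording(t = seq(0, 40, 10), x = 0, y = 0,
                        flags = c(1, 1, 0, 0, 1))
  segs2 <- splitSegments(rec2)
  expect_length(segs2$on_surface, 2L)
  expect_length(segs2$in_air, 1L)

  set.seed(10)
  for (i in 1:40) {
    n <- sample(2:80, 1)
    flags <- sample(c(0, 1), n, replace = TRUE)
    if (!any(flags == 1)) flags[1] <- 1
    rec <- makeRecording(t = seq_len(n) * 10, x = rnorm(n), y = rnorm(n),
                         flags = flags)
    segs <- splitSegments(rec)
    runs <- bruteRuns(flags)
    all <- c(segs$on_surface, segs$in_air)
    # counts per movement type match the run-length encoding
    expect_equal(length(segs$on_surface), sum(sapply(runs, `[[`, "value") == 1))
    expect_equal(length(segs$in_air), sum(sapply(runs, `[[`, "value") == 0))
    # partition: sample counts sum to n, types differ by at most one run
    expect_equal(sum(sapply(all, length)), n)
    expect_lte(abs(length(segs$on_surface) - length(segs$in_air)), 1L)
    # concatenating segments in temporal order reproduces the recording
    starts <- vapply(all, function(s) segmentSamples(s)$t[1], numeric(1))
    ordered <- all[order(starts)]
    rebuilt <- do.call(rbind, lapply(ordered, segmentSamples))
    rownames(rebuilt) <- NULL
    expect_equal(rebuilt, penSamples(rec))
  }
})

test_that("pen lifts are down-transitions and ignore trajectory content", {
  expect_equal(countPenLifts(makeRecording(t = c(0, 10, 20), x = 0, y = 0,
                                           flags = 1)), 0L)
  rec <- makeRecording(t = seq(0, 30, 10), x = 0, y = 0, flags = c(1, 0, 1, 0))
  expect_equal(countPenLifts(rec), 2L)
  expect_equal(countPenLifts(rec, "in_air"), 1L)
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    flags <- sample(c(0, 1), n, replace = TRUE); flags[1] <- 1
    t <- seq_len(n) * 10
    a <- makeRecording(t = t, x = rnorm(n), y = rnorm(n), flags = flags)
    b <- makeRecording(t = t, x = rnorm(n, 100), y = rnorm(n, -50),
                       flags = flags)
    expect_equal(countPenLifts(a), sum(diff(flags) == -1))
    expect_equal(countPenLifts(a), countPenLifts(b))
    # identity: starts and ends on-surface -> lifts = on-surface segments - 1
    if (flags[n] == 1) {
      segs <- splitSegments(a)
      expect_equal(countPenLifts(a), length(segs$on_surface) - 1L)
    }
  }
})

test_that("segment geometry matches hand geometry and its inequalities", {
  single <- splitSegments(makeRecording(t = c(0, 10), x = 0:1, y = 0,
                                        flags = c(1, 0)))$on_surface[[1]]
  expect_equal(segmentGeometry(single),
               c(duration = 0, path_length = 0, vertical_length = 0,
                 horizontal_length = 0, width = 0, height = 0))

  # unit square path: (0,0) (1,0) (1,1) (0,1), 10 ms apart
  sq <- splitSegments(makeRecording(t = seq(0, 30, 10), x = c(0, 1, 1, 0),
                                    y = c(0, 0, 1, 1), flags = 1))$on_surface[[1]]
  g <- segmentGeometry(sq)
  expect_equal(g[["duration"]], 0.03)
  expect_equal(g[["path_length"]], 3)
  expect_equal(g[["horizontal_length"]], 2)
  expect_equal(g[["vertical_length"]], 1)
  expect_equal(g[["width"]], 1)
  expect_equal(g[["height"]], 1)

  set.seed(12)
  for (i in 1:30) {
    n <- sample(2:40, 1)
    seg <- splitSegments(makeRecording(t = seq_len(n) * 10, x = rnorm(n),
                                       y = rnorm(n), flags = 1))$on_surface[[1]]
    g <- segmentGeometry(seg)
    expect_gte(g[["horizontal_length"]], g[["width"]])
    expect_gte(g[["vertical_length"]], g[["height"]])
    expect_gte(g[["path_length"]], max(g[["width"]], g[["height"]]))
    expect_true(all(g >= 0))
  }
})

test_that("segment summaries use population statistics", {
  g1 <- c(duration = 0.1, path_length = 1, vertical_length = 1,
          horizontal_length = 1, width = 1, height = 1)
  s1 <- summarizeSegments(list(g1))
  expect_equal(s1[["seg_duration_mean"]], 0.1)
  expect_equal(s1[["seg_duration_sd"]], 0)
  expect_equal(s1[["seg_duration_max"]], s1[["seg_duration_min"]])

  g2 <- g1; g2["duration"] <- 0.3
  s2 <- summarizeSegments(list(g1, g2))
  expect_equal(s2[["seg_duration_mean"]], 0.2)
  expect_equal(s2[["seg_duration_sd"]], 0.1)   # population form
  expect_length(s2, 30L)
  expect_error(summarizeSegments(list()), "degenerate")

  set.seed(13)
  for (i in 1:20) {
    k <- sample(1:12, 1)
    geoms <- lapply(seq_len(k), function(j)
      abs(rnorm(6)) |> stats::setNames(names(g1)))
    s <- summarizeSegments(geoms)
    durs <- vapply(geoms, `[[`, numeric(1), "duration")
    expect_equal(unname(s[paste0("seg_duration_",
                                 c("mean", "median", "sd", "max", "min"))]),
                 unname(bruteFive(durs)), tolerance = 1e-12)
  }
})

test_that("inclination features follow the fallback and variance rules", {
  one <- splitSegments(makeRecording(t = c(0, 10), x = 0:1, y = 0,
                                     flags = 1))$on_surface
  expect_equal(unname(inclinationFeatures(one)), rep(0, 12))

  # seg1 y = {0, 2}, seg2 y = {1, 3}
  rec <- makeRecording(t = seq(0, 40, 10), x = 0:4, y = c(0, 2, 5, 1, 3),
                       flags = c(1, 1, 0, 1, 1))
  incl <- inclinationFeatures(splitSegments(rec)$on_surface)
  expect_equal(incl[["diff_end_max"]], -1)       # 2 - 3
  expect_equal(incl[["diff_end_min"]], -1)       # 0 - 1
  expect_equal(incl[["var_y_max"]], 0.25)        # population var of {2, 3}
  expect_equal(incl[["diff_preend_max"]], 0)     # < 4 segments -> 0

  # identical per-segment y-ranges -> all diffs and variances 0
  flat <- makeRecording(t = seq(0, 70, 10), x = 0:7,
                        y = c(0, 5, 9, 0, 5, 9, 0, 5),
                        flags = c(1, 1, 0, 1, 1, 0, 1, 1))
  inclFlat <- inclinationFeatures(splitSegments(flat)$on_surface)
  expect_equal(unname(inclFlat[c("diff_end_min", "diff_end_max",
                                 "var_y_min", "var_y_mean")]), rep(0, 4))

  # translating y leaves every inclination feature unchanged
  set.seed(14)
  n <- 40
  flags <- rep(c(1, 1, 1, 0), 10)
  y <- rnorm(n, 0, 20)
  a <- inclinationFeatures(splitSegments(makeRecording(
    t = seq_len(n) * 10, x = rnorm(n), y = y, flags = flags))$on_surface)
  b <- inclinationFeatures(splitSegments(makeRecording(
    t = seq_len(n) * 10, x = rnorm(n), y = y + 500, flags = flags))$on_surface)
  expect_equal(a, b, tolerance = 1e-9)
  expect_error(inclinationFeatures(list()), "degenerate")
})
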