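test_that("the registry decomposes into 12x7 + 6x5 + 19 unique names", {
  on <- featureRegistry("on_surface")
  air <- featureRegistry("in_air")
  expect_length(on, 133L)
  expect_length(air, 112L)
  expect_equal(anyDuplicated(on), 0L)
  # decomposition: 84 signal summaries, 30 segment summaries, 19 scalars
  expect_equal(sum(grepl("_(mean|median|sd|max|min|p05|p95)$", on) &
                   !grepl("^seg_", on) & !grepl("^(diff|var)_", on)), 84L)
  expect_equal(sum(grepl("^seg_", on)), 30L)
  expect_equal(133L - 84L - 30L, 19L)
  # the in-air registry is exactly the on-surface one minus the 21
  # pressure/altitude/azimuth summaries
  dropped <- setdiff(on, air)
  expect_length(dropped, 21L)
  expect_true(all(grepl("^(pressure|altitude|azimuth)_", dropped)))
  expect_equal(air, setdiff(on, dropped))
})

test_that("extraction yields 133 on-surface / 112 in-air finite features", {
  set.seed(20)
  rec <- generateTask("hrackarstvo", dysgraphiaProfile(1))
  fv <- extractTaskFeatures(rec, "on_surface")
  expect_length(fv, 133L)
  expect_equal(names(fv), featureRegistry("on_surface"))
  expect_true(all(is.finite(featureValues(fv))))
  air <- extractTaskFeatures(rec, "in_air")
  expect_length(air, 112L)
  expect_equal(names(air), featureRegistry("in_air"))
  # deterministic: identical recordings yield bit-identical vectors
  expect_identical(featureValues(extractTaskFeatures(rec, "on_surface")),
                   featureValues(fv))
})

test_that("stationary pen gives zero kinematics and constant pressure", {
  rec <- makeRecording(t = seq(0, 90, 10), x = 3, y = 4, flags = 1,
                       pressure = 321)
  fv <- featureValues(extractTaskFeatures(rec, "on_surface"))
  expect_equal(unname(fv[c("velocity_mean", "acceleration_max", "jerk_sd",
                           "velocity_vertical_p95")]), rep(0, 4))
  expect_equal(unname(fv[c("pressure_mean", "pressure_min", "pressure_p95")]),
               rep(321, 3))
  expect_equal(fv[["pen_lifts"]], 0)
  # no in-air segment -> degenerate all-zero 112-vector, fully flagged
  airless <- extractTaskFeatures(rec, "in_air")
  expect_length(airless, 112L)
  expect_true(all(featureValues(airless) == 0))
  expect_setequal(degenerateFeatures(airless), featureRegistry("in_air"))
})

test_that("a session merges to 1176 task-major features", {
  co <- tinyCohort(n = 2, nDys = 1, seed = 21)
  fv <- mergeSessionFeatures(co$sessions[[1]])
  expect_length(fv, 1176L)
  want <- c(as.vector(vapply(taskTemplate(), function(task)
    paste(task, "on_surface", featureRegistry("on_surface"), sep = "."),
    character(133))),
    paste("sentence", "in_air", featureRegistry("in_air"), sep = "."))
  expect_equal(names(fv), want)
  # missing task is named in the error
  broken <- co$sessions[[1]]
  broken@recordings[["leto"]] <- NULL
  expect_error(mergeSessionFeatures(broken), "leto")
  # determinism across identical sessions
  expect_identical(featureValues(mergeSessionFeatures(co$sessions[[1]])),
                   featureValues(fv))
})

test_that("featureMatrix builds a SummarizedExperiment per selector", {
  co <- tinyCohort(n = 3, nDys = 1, seed = 22)
  m <- featureMatrix(co$sessions, tasks = "all")
  expect_s4_class(m, "SummarizedExperiment")
  expect_equal(dim(m), c(1176L, 3L))
  expect_equal(m$label, vapply(co$sessions, function(s) s$label, character(1)))
  expect_equal(unique(SummarizedExperiment::rowData(m)$task[1:133]), "l")
  expect_equal(dim(featureMatrix(co$sessions, tasks = "leto")), c(133L, 3L))
  expect_equal(dim(featureMatrix(co$sessions, tasks = "sentence_in_air")),
               c(112L, 3L))
  expect_equal(dim(featureMatrix(co$sessions, tasks = "sentence_both")),
               c(245L, 3L))
  expect_error(featureMatrix(co$sessions, tasks = "nope"), "unknown task")
})

test_that("standardizer gives zero mean, unit variance, and guards constants", {
  # column [0, 2] -> mean 1, population sd 1
  m <- matrix(c(0, 2), nrow = 1, dimnames = list("f1", c("a", "b")))
  s <- fitStandardizer(m)
  expect_equal(s@means, 1)
  expect_equal(s@sds, 1)

  set.seed(23)
  mat <- matrix(rnorm(50 * 8, sd = 4), nrow = 50,
                dimnames = list(paste0("f", 1:50), paste0("s", 1:8)))
  mat[7, ] <- 3.14                      # constant feature
  st <- fitStandardizer(mat)
  expect_equal(st@zeroVariance, "f7")
  z <- applyStandardizer(mat, st)
  expect_equal(unname(rowMeans(z)), rep(0, 50), tolerance = 1e-10)
  nz <- setdiff(rownames(mat), "f7")
  expect_equal(unname(sqrt(rowMeans(z[nz, ]^2))), rep(1, length(nz)),
               tolerance = 1e-10)
  expect_true(all(z[7, ] == 0))
  # idempotent on non-constant features
  z2 <- applyStandardizer(z, fitStandardizer(z))
  expect_equal(z2[nz, ], z[nz, ], tolerance = 1e-10)
  # train-fitted stats applied to disjoint test data: no refit
  test <- matrix(rnorm(50 * 4, mean = 10), nrow = 50,
                 dimnames = list(paste0("f", 1:50), paste0("t", 1:4)))
  zt <- applyStandardizer(test, st)
  expect_equal(zt[1, 1], (test[1, 1] - st@means[1]) / st@sds[1])
  expect_error(applyStandardizer(mat[1:10, ], st), "do not match")
  expect_error(fitStandardizer(mat[, 1, drop = FALSE]), "degenerate")
})

test_that("feature matrices round-trip through delimited text", {
  co <- tinyCohort(n = 3, nDys = 2, seed = 24)
  m <- featureMatrix(co$sessions, tasks = "le")
  f <- withr::local_tempfile()
  writeFeatureMatrix(m, f)
  back <- readFeatureMatrix(f)
  expect_equal(dim(back), dim(m))
  expect_equal(rownames(back), rownames(m))
  expect_equal(back$label, m$label)
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(m), tolerance = 1e-9)
})

test_that("feature-weight report aggregates external weights by registry name", {
  w <- c("l.on_surface.pen_lifts" = 0.4,
         "leto.on_surface.pen_lifts" = 0.3,
         "sentence.in_air.jerk_p95" = 0.2,
         "le.on_surface.velocity_mean" = 0)
  rep <- featureWeightReport(w)
  expect_equal(nrow(rep$perColumn), 3L)          # zero weights dropped
  expect_equal(rep$aggregated$feature[1], "pen_lifts")
  expect_equal(rep$aggregated$weight[1], 0.7)
  expect_error(featureWeightReport(c(bad = 1)), "task")
})
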