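test_that("metric formulas match their defining arithmetic", {
  expect_equal(classificationMetrics(confusionCounts(10, 10, 0, 0)),
               c(accuracy = 100, specificity = 100, sensitivity = 100))
  expect_equal(classificationMetrics(confusionCounts(3, 4, 1, 2)),
               c(accuracy = 70, specificity = 80, sensitivity = 60))
  expect_error(classificationMetrics(confusionCounts(0, 4, 1, 0)),
               "sensitivity")
  expect_error(classificationMetrics(confusionCounts(3, 0, 0, 2)),
               "specificity")
  expect_error(confusionCounts(-1, 0, 0, 0), "non-negative")
})

test_that("accuracy equals the prevalence-weighted mix of sens and spec", {
  set.seed(30)
  for (i in 1:50) {
    cc <- confusionCounts(sample(1:30, 1), sample(1:30, 1),
                          sample(1:30, 1), sample(1:30, 1))
    m <- classificationMetrics(cc)
    P <- cc@TP + cc@FN; N <- cc@TN + cc@FP
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("hyperparameter grids enumerate the documented candidate sets", {
  ab <- adaBoostGrid()
  expect_equal(nrow(ab), 25L)
  expect_equal(range(ab$n_estimators), c(20L, 500L))
  expect_true(all(diff(ab$n_estimators) == 20L))
  rf <- rfGrid()
  expect_equal(nrow(rf), 500L)            # 25 x 4 x 5
  expect_setequal(unique(rf$min_split), c(2L, 4L, 6L, 8L))
  expect_setequal(unique(rf$max_features), c(5L, 10L, 20L, 30L, 40L))
  sv <- svmGrid()
  expect_equal(nrow(sv), 100L)            # 10 x 10 odd powers of two
  expect_equal(sort(unique(sv$cost)), 2^seq(-9, 9, by = 2))
  expect_equal(sort(unique(sv$gamma)), 2^seq(-9, 9, by = 2))
})

test_that("default classifiers carry the tuned hyperparameters", {
  d <- defaultClassifiers()
  expect_equal(d$adaboost$params$n_estimators, 340L)
  expect_equal(d$rf$params[c("n_estimators", "min_split", "max_features")],
               list(n_estimators = 60L, min_split = 4L, max_features = 5L))
  expect_equal(d$svm$params$cost, 4)
  expect_equal(d$svm$params$gamma, 2^-9)
})

test_that("the AdaBoost stump ensemble learns a separable rule", {
  set.seed(31)
  n <- 60
  x <- cbind(noise1 = rnorm(n), signal = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
             noise2 = rnorm(n))
  y <- factor(rep(c("control", "dysgraphia"), each = n / 2))
  fit <- fitAdaBoost(x, y, nEstimators = 30)
  expect_gt(mean(predict(fit, x) == y), 0.95)
  # generalizes to fresh draws from the same rule
  x2 <- cbind(noise1 = rnorm(n), signal = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
              noise2 = rnorm(n))
  expect_gt(mean(predict(fit, x2) == y), 0.85)
})

test_that("cross-validation is seed-deterministic and leakage-free", {
  set.seed(32)
  n <- 60
  x <- matrix(rnorm(n * 15), n, dimnames = list(NULL, paste0("f", 1:15)))
  y <- factor(rep(c("control", "dysgraphia"), each = n / 2))
  r1 <- repeatedStratifiedCV(x, defaultClassifiers()$rf, folds = 5,
                             repeats = 3, seed = 99, labels = y)
  r2 <- repeatedStratifiedCV(x, defaultClassifiers()$rf, folds = 5,
                             repeats = 3, seed = 99, labels = y)
  expect_identical(cvRepeats(r1), cvRepeats(r2))
  expect_equal(cvProtocol(r1)$folds, 5L)
  # leakage canary: the label itself as a feature -> perfect accuracy
  xx <- cbind(x, label_leak = as.numeric(y == "dysgraphia"))
  rl <- repeatedStratifiedCV(xx, defaultClassifiers()$rf, folds = 5,
                             repeats = 2, seed = 1, labels = y)
  expect_equal(cvMetrics(rl)$mean, rep(100, 3))
  # null features on permuted labels hover near chance, never near 100
  rn <- repeatedStratifiedCV(x, defaultClassifiers()$rf, folds = 5,
                             repeats = 3, seed = 2, labels = y)
  expect_lt(cvMetrics(rn)$mean[1], 75)
  few <- c(1:3, 31:33)                  # 3 per class, fewer than the 5 folds
  expect_error(repeatedStratifiedCV(x[few, ], folds = 5, labels = y[few]),
               "stratification error")
})

test_that("grid search scores every candidate and breaks ties first-wins", {
  set.seed(33)
  n <- 40
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 3] <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  y <- factor(rep(c("control", "dysgraphia"), each = n / 2))
  tiny <- structure(data.frame(n_estimators = c(10L, 20L)), family = "adaboost")
  gs <- gridSearch(x, tiny, folds = 4, repeats = 1, seed = 1, labels = y)
  expect_equal(nrow(gs$scores), 2L)
  expect_true(gs$accuracy >= max(gs$scores$accuracy) - 1e-9)
  # perfect separation ties both candidates -> first in enumeration wins
  if (gs$scores$accuracy[1] == gs$scores$accuracy[2])
    expect_equal(gs$best$params$n_estimators, 10L)
  expect_error(gridSearch(x, data.frame(), labels = y), "non-empty")
})

test_that("the benchmark report has one row per (cell, classifier)", {
  co <- tinyCohort(n = 12, nDys = 6, seed = 34)
  rep <- runBenchmark(co$sessions, tasks = c("le", "all"),
                      classifiers = defaultClassifiers()["rf"],
                      folds = 3, repeats = 2, seed = 7)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$task, c("le", "all"))
  expect_true(all(rep$acc_mean >= 0 & rep$acc_mean <= 100))
  # strong planted effect: merged features are near-perfectly separable
  expect_gte(rep$acc_mean[rep$task == "all"], 90)
  expect_error(runBenchmark(co$sessions, tasks = "bogus"), "unknown benchmark")
})
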