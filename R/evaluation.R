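#' Accuracy, specificity and sensitivity from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN) * 100`, `specificity = TN/(TN+FP) *
#' 100`, `sensitivity = TP/(TP+FN) * 100`, with dysgraphia as the positive
#' class.
#'
#' @param cc a [ConfusionCounts-class].
#' @return Named numeric vector `accuracy, specificity, sensitivity`
#'   (percent).
#' @export
#' @examples
#' classificationMetrics(confusionCounts(3, 4, 1, 2))  # 70, 80, 60
classificationMetrics <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  tot <- cc@TP + cc@TN + cc@FP + cc@FN
  if (tot == 0)
    stop("undefined metric 'accuracy': no evaluated subjects", call. = FALSE)
  if (cc@TN + cc@FP == 0)
    stop("undefined metric 'specificity': TN + FP is zero", call. = FALSE)
  if (cc@TP + cc@FN == 0)
    stop("undefined metric 'sensitivity': TP + FN is zero", call. = FALSE)
  c(accuracy = 100 * (cc@TP + cc@TN) / tot,
    specificity = 100 * cc@TN / (cc@TN + cc@FP),
    sensitivity = 100 * cc@TP / (cc@TP + cc@FN))
}

#' Hyperparameter grids of the benchmark
#'
#' The search spaces used when tuning the three classifiers: AdaBoost
#' estimator counts 20 to 500 in steps of 20 (25 candidates); random forest
#' over the product of `n_estimators` = 20,40,...,500, `min_split` =
#' 2,4,6,8 and `max_features` = 5,10,20,30,40 (500 candidates); SVM cost and
#' gamma over the odd powers of two from 2^-9 to 2^9 (10 x 10 candidates).
#'
#' @return data.frame with one row per candidate and a `family` attribute.
#' @export
#' @examples
#' nrow(adaBoostGrid())  # 25
#' nrow(rfGrid())        # 500
#' nrow(svmGrid())       # 100
adaBoostGrid <- function() {
  structure(data.frame(n_estimators = seq(20L, 500L, by = 20L)),
            family = "adaboost")
}

#' @rdname adaBoostGrid
#' @export
rfGrid <- function() {
  structure(expand.grid(n_estimators = seq(20L, 500L, by = 20L),
                        min_split = c(2L, 4L, 6L, 8L),
                        max_features = c(5L, 10L, 20L, 30L, 40L),
                        KEEP.OUT.ATTRS = FALSE),
            family = "rf")
}

#' @rdname adaBoostGrid
#' @export
svmGrid <- function() {
  pw <- 2^seq(-9, 9, by = 2)
  structure(expand.grid(cost = pw, gamma = pw, KEEP.OUT.ATTRS = FALSE),
            family = "svm")
}

#' Classifier specification
#'
#' A classifier family plus its hyperparameters. `defaultClassifiers()`
#' returns the benchmark's three models at their tuned settings: AdaBoost
#' with 340 estimators; random forest with 60 trees, minimum split size 4
#' and 5 features per split; RBF SVM with C = 4 and gamma = 2^-9.
#'
#' @param family `"adaboost"`, `"rf"` or `"svm"`.
#' @param ... named hyperparameters (see [adaBoostGrid()] and friends for
#'   the recognised names per family).
#' @return List of class `classifierSpec`.
#' @export
classifierSpec <- function(family = c("adaboost", "rf", "svm"), ...) {
  family <- match.arg(family)
  structure(list(family = family, params = list(...)),
            class = "classifierSpec")
}

#' @rdname classifierSpec
#' @export
defaultClassifiers <- function() {
  list(adaboost = classifierSpec("adaboost", n_estimators = 340L),
       rf = classifierSpec("rf", n_estimators = 60L, min_split = 4L,
                           max_features = 5L),
       svm = classifierSpec("svm", cost = 4, gamma = 2^-9))
}

.trainClassifier <- function(spec, x, y) {
  p <- spec$params
  switch(spec$family,
    adaboost = fitAdaBoost(x, y, nEstimators = p$n_estimators %||% 340L),
    rf = randomForest::randomForest(
      x = x, y = y,
      ntree = p$n_estimators %||% 60L,
      nodesize = p$min_split %||% 4L,
      mtry = min(p$max_features %||% 5L, ncol(x))),
    svm = e1071::svm(x = x, y = y, kernel = "radial",
                     cost = p$cost %||% 4, gamma = p$gamma %||% 2^-9,
                     scale = FALSE),
    stop("unknown classifier family '", spec$family, "'", call. = FALSE))
}

.predictClassifier <- function(model, x) {
  if (inherits(model, "adaboostStumps")) predict(model, x)
  else predict(model, x)
}

.extractXY <- function(m, labels = NULL) {
  if (is(m, "SummarizedExperiment")) {
    x <- t(SummarizedExperiment::assay(m))
    y <- m$label
  } else {
    x <- as.matrix(m)
    y <- labels
  }
  if (is.null(y)) stop("labels are required", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("labels must be binary, got levels: ",
         paste(levels(y), collapse = ", "), call. = FALSE)
  # positive class = dysgraphia when present, else the second level
  if ("dysgraphia" %in% levels(y))
    y <- stats::relevel(y, ref = setdiff(levels(y), "dysgraphia")[1L])
  list(x = x, y = y)
}

.stratifiedFolds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds)
      stop("stratification error: class '", cl, "' has ", length(idx),
           " member(s), need >= ", folds, call. = FALSE)
    assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  assign
}

.confusionFromPredictions <- function(truth, pred, positive) {
  confusionCounts(TP = sum(truth == positive & pred == positive),
                  TN = sum(truth != positive & pred != positive),
                  FP = sum(truth != positive & pred == positive),
                  FN = sum(truth == positive & pred != positive))
}

#' Repeated stratified k-fold cross-validation
#'
#' The benchmark protocol: per repeat, subjects are assigned to stratified
#' folds (class proportions preserved); for each fold the per-feature
#' standardizer is fitted on the training folds only and applied unchanged
#' to the held-out fold, the classifier is trained and the fold predicted;
#' the pooled predictions of a repeat give one confusion matrix and one
#' accuracy/specificity/sensitivity triple. The result reports the mean and
#' standard deviation of each metric across repeats and is fully
#' reproducible from the seed.
#'
#' @param m feature matrix: a `SummarizedExperiment` from [featureMatrix()]
#'   (with `label` in `colData`), or a subjects x features numeric matrix
#'   plus `labels`.
#' @param spec a [classifierSpec()].
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param seed integer RNG seed.
#' @param labels label vector when `m` is a plain matrix.
#' @param standardize fit/apply the per-feature z-scoring inside each fold
#'   (default `TRUE`).
#' @return A [CVResult-class].
#' @export
repeatedStratifiedCV <- function(m, spec = defaultClassifiers()$rf,
                                 folds = 10L, repeats = 10L, seed = 1L,
                                 labels = NULL, standardize = TRUE) {
  xy <- .extractXY(m, labels)
  x <- xy$x; y <- xy$y
  positive <- levels(y)[2L]
  set.seed(seed)
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    foldOf <- .stratifiedFolds(y, folds)
    pred <- factor(rep(levels(y)[1L], length(y)), levels = levels(y))
    for (f in seq_len(folds)) {
      test <- foldOf == f
      xtr <- x[!test, , drop = FALSE]
      xte <- x[test, , drop = FALSE]
      if (standardize) {
        s <- fitStandardizer(t(xtr))
        xtr <- t(applyStandardizer(t(xtr), s))
        xte <- t(applyStandardizer(t(xte), s))
      }
      model <- .trainClassifier(spec, xtr, y[!test])
      pred[test] <- .predictClassifier(model, xte)
    }
    met <- classificationMetrics(.confusionFromPredictions(y, pred, positive))
    rows[[r]] <- data.frame(repeat_ = r, accuracy = met[["accuracy"]],
                            specificity = met[["specificity"]],
                            sensitivity = met[["sensitivity"]])
  }
  perRepeat <- do.call(rbind, rows)
  met <- c("accuracy", "specificity", "sensitivity")
  means <- vapply(perRepeat[met], mean, numeric(1))
  sds <- vapply(perRepeat[met], function(v) if (length(v) > 1) sd(v) else 0,
                numeric(1))
  new("CVResult", perRepeat = perRepeat, means = means, sds = sds,
      protocol = list(folds = as.integer(folds),
                      repeats = as.integer(repeats), seed = seed,
                      classifier = spec$family))
}

#' Grid search over classifier hyperparameters
#'
#' Evaluates every grid candidate with the cross-validation protocol on the
#' supplied (training) data and returns the candidate with the highest mean
#' accuracy; ties break deterministically to the earliest candidate in
#' enumeration order.
#'
#' @param m,labels feature matrix and labels as in [repeatedStratifiedCV()].
#' @param grid a grid from [adaBoostGrid()], [rfGrid()] or [svmGrid()] (any
#'   data.frame with a `family` attribute works).
#' @param folds,repeats,seed CV protocol for scoring each candidate
#'   (`repeats` defaults to 1 here; scoring 500 candidates at 10 repeats is
#'   rarely worth it).
#' @return List: `best` (a [classifierSpec()]), `accuracy`, and `scores`
#'   (the grid with an accuracy column).
#' @export
gridSearch <- function(m, grid, folds = 10L, repeats = 1L, seed = 1L,
                       labels = NULL) {
  family <- attr(grid, "family")
  if (is.null(family) || !nrow(grid))
    stop("grid must be non-empty and carry a 'family' attribute",
         call. = FALSE)
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- do.call(classifierSpec, c(list(family = family),
                                      as.list(grid[i, , drop = FALSE])))
    res <- repeatedStratifiedCV(m, spec, folds = folds, repeats = repeats,
                                seed = seed, labels = labels)
    acc[i] <- res@means[["accuracy"]]
  }
  best <- which.max(acc)   # first maximum = earliest in enumeration order
  scores <- cbind(grid, accuracy = acc)
  list(best = do.call(classifierSpec, c(list(family = family),
                                        as.list(grid[best, , drop = FALSE]))),
       accuracy = acc[best], scores = scores)
}

BENCHMARK_CELLS <- c(taskTemplate(), "sentence_both", "all")

#' Run the per-task and merged classification benchmark
#'
#' For every requested feature set (each single task's 133 on-surface
#' features, the sentence with its in-air features added, and the merged
#' 1176-feature vector) and every classifier, runs repeated stratified
#' cross-validation and collects the accuracy / specificity / sensitivity
#' means and standard deviations into one table.
#'
#' @param sessions list of labelled, complete [Session-class] objects.
#' @param tasks character vector of cells to evaluate: task ids,
#'   `"sentence_both"`, `"all"` — default all ten benchmark cells.
#' @param classifiers named list of [classifierSpec()] (default
#'   [defaultClassifiers()]).
#' @param folds,repeats,seed CV protocol.
#' @param opts a [kinematicsOptions()].
#' @return data.frame with one row per (cell, classifier): means and sds of
#'   the three metrics.
#' @export
runBenchmark <- function(sessions, tasks = BENCHMARK_CELLS,
                         classifiers = defaultClassifiers(),
                         folds = 10L, repeats = 10L, seed = 1L,
                         opts = kinematicsOptions()) {
  bad <- setdiff(tasks, BENCHMARK_CELLS)
  if (length(bad))
    stop("unknown benchmark cell(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(names(classifiers)))
    names(classifiers) <- vapply(classifiers, `[[`, character(1), "family")
  rows <- list()
  for (cell in tasks) {
    m <- featureMatrix(sessions, tasks = cell, opts = opts)
    for (cl in names(classifiers)) {
      res <- repeatedStratifiedCV(m, classifiers[[cl]], folds = folds,
                                  repeats = repeats, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        task = cell, classifier = cl,
        acc_mean = res@means[["accuracy"]], acc_sd = res@sds[["accuracy"]],
        spe_mean = res@means[["specificity"]], spe_sd = res@sds[["specificity"]],
        sen_mean = res@means[["sensitivity"]], sen_sd = res@sds[["sensitivity"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
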