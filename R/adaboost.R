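# Discrete AdaBoost (AdaBoost.M1 / two-class SAMME) on depth-1 decision
# stumps. Each boosting round does an exhaustive weighted search over every
# (feature, threshold, polarity) stump via column-wise cumulative sums on
# presorted feature orders, so a round costs O(n * p) after an O(p n log n)
# presort per training set.

# column-wise cumsum of an n x p matrix without apply()
.colCumsum <- function(m) {
  cs <- matrix(cumsum(m), nrow(m), ncol(m))
  offs <- c(0, cs[nrow(m), -ncol(m)])
  cs - rep(offs, each = nrow(m))
}

#' Fit an AdaBoost stump ensemble
#'
#' Binary discrete AdaBoost with decision stumps (single-threshold,
#' single-feature classifiers) as weak learners. Rounds where the best stump
#' is no better than chance stop the ensemble early; a perfect stump is kept
#' with a capped vote weight.
#'
#' @param x numeric matrix, subjects x features.
#' @param y factor with exactly two levels; the *second* level is the
#'   positive class.
#' @param nEstimators number of boosting rounds (default 340).
#' @return Object of class `adaboostStumps` with the stump table and factor
#'   levels; supports [predict()].
#' @export
fitAdaBoost <- function(x, y, nEstimators = 340L) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, nrow(x) == length(y))
  n <- nrow(x); p <- ncol(x)
  yy <- ifelse(as.integer(y) == 2L, 1, -1)

  ord <- matrix(0L, n, p)
  for (j in seq_len(p)) ord[, j] <- order(x[, j])
  ordFlat <- ord + rep((seq_len(p) - 1L) * n, each = n)   # index into x / w
  xs <- matrix(x[ordFlat], n, p)                          # sorted values
  posMask <- matrix(yy[ord] == 1, n, p)
  validCut <- rbind(xs[-1L, , drop = FALSE] != xs[-n, , drop = FALSE], FALSE)

  w <- rep(1 / n, n)
  stumps <- vector("list", nEstimators)
  for (m in seq_len(nEstimators)) {
    wOrd <- matrix(w[ord], n, p)
    cumP <- .colCumsum(wOrd * posMask)
    cumN <- .colCumsum(wOrd * !posMask)
    wN <- sum(w[yy == -1])
    # err(k, j): threshold after sorted position k, predict +1 above
    err <- cumP + (wN - cumN)
    err[!validCut] <- 0.5
    errFlip <- 1 - err
    i1 <- which.min(err); i2 <- which.min(errFlip)
    if (err[i1] <= errFlip[i2]) { best <- i1; polarity <- 1; e <- err[i1] }
    else { best <- i2; polarity <- -1; e <- errFlip[i2] }
    if (e >= 0.5) break                      # nothing better than chance
    k <- (best - 1L) %% n + 1L
    j <- (best - 1L) %/% n + 1L
    thr <- (xs[k, j] + xs[k + 1L, j]) / 2
    e <- min(max(e, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - e) / e)
    h <- polarity * ifelse(x[, j] > thr, 1, -1)
    w <- w * exp(-alpha * yy * h)
    w <- w / sum(w)
    stumps[[m]] <- c(feature = j, threshold = thr, polarity = polarity,
                     alpha = alpha)
    if (e <= 1e-10) break
  }
  stumps <- stumps[!vapply(stumps, is.null, logical(1))]
  structure(list(stumps = do.call(rbind, stumps), levels = levels(y),
                 nEstimators = nEstimators),
            class = "adaboostStumps")
}

#' @rdname fitAdaBoost
#' @param object fitted `adaboostStumps` model.
#' @param newdata numeric matrix, subjects x features.
#' @param ... ignored.
#' @return `predict()`: factor of predicted classes.
#' @export
predict.adaboostStumps <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  st <- object$stumps
  if (is.null(st) || !nrow(st))
    return(factor(rep(object$levels[1L], nrow(newdata)),
                  levels = object$levels))
  score <- rep(0, nrow(newdata))
  for (m in seq_len(nrow(st)))
    score <- score + st[m, "alpha"] * st[m, "polarity"] *
      ifelse(newdata[, st[m, "feature"]] > st[m, "threshold"], 1, -1)
  factor(object$levels[ifelse(score > 0, 2L, 1L)], levels = object$levels)
}
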