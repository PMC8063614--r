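#' Threshold classification metrics
#'
#' Precision, recall and F1 at a score threshold:
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2 * precision * recall / (precision + recall).
#' A metric with zero denominator is reported as 0 and flagged in
#' `undefined`.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels, same length.
#' @param threshold scores > threshold predict class 1 (default 0.5).
#' @return list with `precision`, `recall`, `f1`, `counts` (TP/FP/TN/FN) and
#'   `undefined` (character vector of flagged metrics).
#' @export
binaryMetrics <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  undefined <- character()
  precision <- if (tp + fp == 0) { undefined <- c(undefined, "precision"); 0 } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { undefined <- c(undefined, "recall"); 0 } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) { undefined <- c(undefined, "f1"); 0 } else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn), undefined = undefined)
}

#' Area under the ROC and precision-recall curves
#'
#' AUC is computed from the midrank (Wilcoxon) statistic — the probability
#' that a random positive outscores a random negative, ties counted half —
#' which equals trapezoidal ROC integration. AUPR is the step-wise
#' integration of the precision-recall curve (average precision over the
#' positives in decreasing-score order).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return list with `auc` and `aupr`.
#' @export
aucAupr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  nP <- sum(labels == 1); nN <- sum(labels == 0)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks
  auc <- (sum(r[labels == 1]) - nP * (nP + 1) / 2) / (nP * nN)
  ord <- order(-scores)
  lab <- labels[ord]
  cumTP <- cumsum(lab)
  precisionAt <- cumTP / seq_along(lab)
  aupr <- sum(precisionAt[lab == 1]) / nP
  list(auc = auc, aupr = aupr)
}

.foldMetrics <- function(scores, labels, threshold) {
  bm <- binaryMetrics(scores, labels, threshold)
  aa <- aucAupr(scores, labels)
  c(auc = aa$auc, aupr = aa$aupr, precision = bm$precision,
    recall = bm$recall, f1 = bm$f1)
}

#' Stratified k-fold cross-validation of the stacking ensemble
#'
#' Samples are partitioned into `folds` near-equal stratified groups; each
#' fold in turn is held out, the full ensemble (four forests + logistic
#' meta-learner) is fitted on the remainder, and AUC, AUPR, precision,
#' recall and F1 are computed on the held-out scores.
#'
#' @param cross a [CrossFeatureSet-class].
#' @param labels binary 0/1 vector.
#' @param folds number of folds (>= 2, default 5).
#' @param seed integer seed for fold assignment and model fitting.
#' @param forestCfg a [forestConfig()].
#' @param stackFolds internal stacking folds (default 5).
#' @param threshold classification threshold (default 0.5).
#' @return list of class "pmdfiCV": `perFold` (data.frame of per-fold
#'   metrics), `mean` (named numeric), `foldId`, `scores` (out-of-fold final
#'   scores in input order), `seed`, `config`.
#' @export
crossValidate <- function(cross, labels, folds = 5L, seed = 1L,
                          forestCfg = forestConfig(), stackFolds = 5L,
                          threshold = 0.5) {
  stopifnot(is(cross, "CrossFeatureSet"))
  labels <- as.integer(labels)
  if (folds < 2) stop("folds must be >= 2")
  if (length(unique(labels)) < 2L) stop("both classes required")
  foldId <- stratifiedFolds(labels, folds, deriveSeed(seed, 1L))
  perFold <- matrix(NA_real_, folds, 5L,
                    dimnames = list(NULL, c("auc", "aupr", "precision", "recall", "f1")))
  oofScores <- numeric(length(labels))
  for (f in seq_len(folds)) {
    test <- foldId == f
    if (length(unique(labels[test])) < 2L || length(unique(labels[!test])) < 2L)
      stop(sprintf("fold %d lacks both classes; use stratified labels", f))
    sub <- function(b, idx) crossBlock(cross, b)[idx, , drop = FALSE]
    trainCross <- new("CrossFeatureSet",
                      D1 = sub("D1", !test), D2 = sub("D2", !test),
                      D3 = sub("D3", !test), D4 = sub("D4", !test))
    testCross <- new("CrossFeatureSet",
                     D1 = sub("D1", test), D2 = sub("D2", test),
                     D3 = sub("D3", test), D4 = sub("D4", test))
    model <- fitPMDFI(trainCross, labels[!test], forestCfg, stackFolds,
                      seed = deriveSeed(seed, 1000L + f))
    sc <- predictPairs(model, testCross)$final
    oofScores[test] <- sc
    perFold[f, ] <- .foldMetrics(sc, labels[test], threshold)
  }
  structure(list(
    perFold = as.data.frame(perFold),
    mean = colMeans(perFold),
    foldId = foldId, scores = oofScores, seed = as.integer(seed),
    config = list(folds = folds, forestCfg = unclass(forestCfg),
                  stackFolds = stackFolds, threshold = threshold)),
    class = "pmdfiCV")
}

#' @export
print.pmdfiCV <- function(x, ...) {
  cat(sprintf("PMDFI %d-fold cross-validation (seed %d)\n",
              x$config$folds, x$seed))
  print(round(x$mean, 4))
  invisible(x)
}

# single-forest CV on one block, reusing a fixed fold assignment
.singleForestCV <- function(block, labels, foldId, forestCfg, seed, threshold) {
  folds <- max(foldId)
  perFold <- matrix(NA_real_, folds, 5L,
                    dimnames = list(NULL, c("auc", "aupr", "precision", "recall", "f1")))
  for (f in seq_len(folds)) {
    test <- foldId == f
    fr <- .fitForest(block[!test, , drop = FALSE], labels[!test], forestCfg,
                     deriveSeed(seed, 3000L + f))
    sc <- .forestProb(fr, block[test, , drop = FALSE])
    perFold[f, ] <- .foldMetrics(sc, labels[test], threshold)
  }
  colMeans(perFold)
}

#' Per-cross-feature ablation
#'
#' Runs single-forest cross-validation separately on each cross-feature
#' block D1..D4 and the full stacking ensemble, all under the identical fold
#' assignment, to show what each interaction pairing contributes and that
#' integrating all four is at least as good as the best single one.
#'
#' @inheritParams crossValidate
#' @return data.frame with rows D1, D2, D3, D4, PMDFI and columns auc, aupr,
#'   precision, recall, f1. The fold assignment is attached as attribute
#'   `foldId`.
#' @export
ablationCrossFeatures <- function(cross, labels, folds = 5L, seed = 1L,
                                  forestCfg = forestConfig(),
                                  stackFolds = 5L, threshold = 0.5) {
  labels <- as.integer(labels)
  foldId <- stratifiedFolds(labels, folds, deriveSeed(seed, 1L))
  rows <- lapply(seq_len(4L), function(k)
    .singleForestCV(crossBlock(cross, .blockNames[k]), labels, foldId,
                    forestCfg, deriveSeed(seed, 50L * k), threshold))
  cv <- crossValidate(cross, labels, folds, seed, forestCfg, stackFolds,
                      threshold)
  stopifnot(identical(cv$foldId, foldId))  # same protocol for every row
  out <- as.data.frame(do.call(rbind, c(rows, list(cv$mean))))
  rownames(out) <- c(.blockNames, "PMDFI")
  attr(out, "foldId") <- foldId
  out
}
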