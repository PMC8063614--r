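test_that("threshold metrics match their defining ratios", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.2)
  labels <- c(1, 0, 1, 1, 0)
  m <- binaryMetrics(scores, labels, 0.5)
  expect_equal(unname(m$counts), c(2, 1, 1, 1))  # TP FP TN FN
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # perfect scores
  p <- binaryMetrics(c(0.9, 0.1), c(1, 0))
  expect_equal(c(p$precision, p$recall, p$f1), c(1, 1, 1))
  # degenerate: nothing predicted positive -> flagged zeros, no NaN
  z <- binaryMetrics(c(0.1, 0.2), c(1, 0), 0.5)
  expect_equal(z$precision, 0)
  expect_true("precision" %in% z$undefined)
  expect_error(binaryMetrics(numeric(), integer()), "empty")
})

test_that("AUC/AUPR match hand-computed values and reject one-class input", {
  expect_equal(aucAupr(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  # 3 concordant of 4 positive-negative pairs
  expect_equal(aucAupr(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(aucAupr(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("rank-statistic AUC equals brute-force concordance, ties included", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)  # coarse grid forces ties
    expect_equal(aucAupr(scores, labels)$auc, bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to permutation of (score, label) pairs", {
  set.seed(11)
  scores <- runif(100); labels <- rbinom(100, 1, 0.5)
  perm <- sample(100)
  a <- aucAupr(scores, labels)
  b <- aucAupr(scores[perm], labels[perm])
  expect_equal(a, b, tolerance = 1e-12)
  m1 <- binaryMetrics(scores, labels); m2 <- binaryMetrics(scores[perm], labels[perm])
  expect_equal(m1$counts, m2$counts)
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- runif(300); labels <- rbinom(300, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucAupr(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("cross-validation is stratified, near-equal, deterministic and errors sanely", {
  fx <- smallCrossFixture(n = 100)
  cv <- crossValidate(fx$cross, fx$labels, folds = 5, seed = 3,
                      forestConfig(nTrees = 60L), stackFolds = 3)
  expect_equal(unname(table(cv$foldId)), rep(20L, 5), ignore_attr = TRUE)
  # stratification: each fold holds both classes evenly
  for (f in 1:5)
    expect_equal(sum(fx$labels[cv$foldId == f]), 10)
  expect_equal(nrow(cv$perFold), 5)
  expect_true(all(as.matrix(cv$perFold) >= 0 & as.matrix(cv$perFold) <= 1))
  cv2 <- crossValidate(fx$cross, fx$labels, folds = 5, seed = 3,
                       forestConfig(nTrees = 60L), stackFolds = 3)
  expect_identical(cv$perFold, cv2$perFold)
  expect_error(crossValidate(fx$cross, fx$labels, folds = 1), "folds")
  expect_error(crossValidate(fx$cross, rep(1L, 100), folds = 5), "both classes")
})

test_that("ablation runs every row under the identical fold assignment", {
  fx <- smallCrossFixture(n = 80)
  abl <- ablationCrossFeatures(fx$cross, fx$labels, folds = 4, seed = 2,
                               forestConfig(nTrees = 40L), stackFolds = 3)
  expect_equal(rownames(abl), c("D1", "D2", "D3", "D4", "PMDFI"))
  expect_false(is.null(attr(abl, "foldId")))
  expect_true(all(as.matrix(abl) >= 0 & as.matrix(abl) <= 1))
  # on this symmetric fixture every block carries signal
  expect_true(all(abl$auc > 0.9))
})

test_that("ablation ranks a signal-free view pair below the informative one", {
  # FS/SS views are pure noise; only the GIP-derived views separate classes,
  # so D4 (both GIP views) must beat D1 (no GIP view)
  set.seed(21)
  n <- 120; w <- 6
  labels <- rep(c(0L, 1L), length.out = n)
  noiseView <- function() matrix(rnorm(n * w), n, w)
  signalView <- function() {
    m <- matrix(rnorm(n * w, sd = 0.3), n, w)
    m[labels == 1, ] <- m[labels == 1, ] + 1.5
    m
  }
  cross <- buildCrossFeatures(noiseView(), noiseView(), signalView(), signalView())
  abl <- ablationCrossFeatures(cross, labels, folds = 4, seed = 5,
                               forestConfig(nTrees = 60L), stackFolds = 3)
  expect_gt(abl["D4", "auc"], abl["D1", "auc"])
  # centroid oracle confirms which views carry signal
  D4 <- crossBlock(cross, "D4")
  c1 <- colMeans(D4[labels == 1, ]); c0 <- colMeans(D4[labels == 0, ])
  s <- sqrt(rowSums(sweep(D4, 2, c0)^2)) - sqrt(rowSums(sweep(D4, 2, c1)^2))
  expect_gt(aucAupr(s, labels)$auc, 0.9)
})
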