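#' Random-forest configuration for the base learners
#'
#' @param nTrees trees per forest (default 300).
#' @param mtry variables tried per split; default floor(sqrt(block width)).
#' @param minNode minimal terminal-node size (default 1).
#' @return named list of class "forestConfig".
#' @export
forestConfig <- function(nTrees = 300L, mtry = NULL, minNode = 1L) {
  if (nTrees < 1) stop("nTrees must be >= 1")
  structure(list(nTrees = as.integer(nTrees), mtry = mtry,
                 minNode = as.integer(minNode)),
            class = "forestConfig")
}

.blockNames <- c("D1", "D2", "D3", "D4")

.blockDF <- function(block) {
  df <- as.data.frame(block)
  colnames(df) <- paste0("V", seq_len(ncol(block)))
  df
}

.fitForest <- function(block, labels, cfg, seed) {
  df <- .blockDF(block)
  df$.y <- factor(labels, levels = c(0, 1))
  ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = cfg$nTrees,
    mtry = cfg$mtry %||% max(1L, floor(sqrt(ncol(block)))),
    min.node.size = cfg$minNode, seed = seed, num.threads = 1,
    verbose = FALSE)
}

.forestProb <- function(forest, block) {
  p <- stats::predict(forest, data = .blockDF(block),
                      num.threads = 1, verbose = FALSE)$predictions
  p[, "1"]
}

#' Fit the stacking ensemble: four forests + logistic meta-learner
#'
#' One probability random forest is trained per cross-feature block. The
#' meta-learner is a logistic regression over the four base probabilities;
#' to avoid the meta-learner seeing optimistic in-sample scores, its training
#' features are out-of-fold base probabilities from `stackFolds` internal
#' stratified splits (`stacking = "oof"`). The `"naive"` mode uses in-sample
#' base scores instead, for comparison. The four forests are refit on all
#' training data after the meta-features are collected.
#'
#' @param cross a [CrossFeatureSet-class] of training pairs.
#' @param labels binary 0/1 vector, one per sample; both classes required.
#' @param forestCfg a [forestConfig()].
#' @param stackFolds internal folds for out-of-fold stacking (default 5).
#' @param seed integer seed governing fold splits and forest randomness.
#' @param stacking "oof" (default) or "naive".
#' @return a [PMDFIModel-class].
#' @export
fitPMDFI <- function(cross, labels, forestCfg = forestConfig(),
                     stackFolds = 5L, seed = 1L,
                     stacking = c("oof", "naive")) {
  stopifnot(is(cross, "CrossFeatureSet"))
  stacking <- match.arg(stacking)
  labels <- as.integer(labels)
  n <- nrow(crossBlock(cross, "D1"))
  if (length(labels) != n) stop("labels length must match sample count")
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes")
  if (n < stackFolds) stop("fewer samples than stackFolds")
  blocks <- lapply(.blockNames, function(b) crossBlock(cross, b))

  meta <- matrix(NA_real_, n, 4L)
  if (stacking == "oof") {
    foldId <- stratifiedFolds(labels, stackFolds, deriveSeed(seed, 11L))
    for (f in seq_len(stackFolds)) {
      trainIdx <- foldId != f
      for (k in seq_len(4L)) {
        fr <- .fitForest(blocks[[k]][trainIdx, , drop = FALSE],
                         labels[trainIdx], forestCfg,
                         deriveSeed(seed, 20L * f + k))
        meta[!trainIdx, k] <- .forestProb(fr, blocks[[k]][!trainIdx, , drop = FALSE])
      }
    }
  }
  forests <- lapply(seq_len(4L), function(k)
    .fitForest(blocks[[k]], labels, forestCfg, deriveSeed(seed, 7L + k)))
  if (stacking == "naive")
    for (k in seq_len(4L)) meta[, k] <- .forestProb(forests[[k]], blocks[[k]])

  mdf <- data.frame(p1 = meta[, 1], p2 = meta[, 2], p3 = meta[, 3],
                    p4 = meta[, 4], .y = labels)
  fit <- suppressWarnings(
    stats::glm(.y ~ p1 + p2 + p3 + p4, family = stats::binomial(), data = mdf))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  new("PMDFIModel", forests = forests, weights = unname(co[2:5]),
      intercept = unname(co[1]), stackFolds = as.integer(stackFolds),
      forestConfig = unclass(forestCfg), seed = as.integer(seed))
}

#' Score pairs with a fitted PMDFI model
#'
#' @param model a [PMDFIModel-class].
#' @param cross a [CrossFeatureSet-class]; block widths must match training.
#' @return data.frame with the four base probabilities `p1..p4` and the
#'   meta-learner's `final` score sigmoid(b + w . p), all in [0, 1].
#' @export
predictPairs <- function(model, cross) {
  stopifnot(is(model, "PMDFIModel"), is(cross, "CrossFeatureSet"))
  blocks <- lapply(.blockNames, function(b) crossBlock(cross, b))
  for (k in seq_len(4L)) {
    need <- length(model@forests[[k]]$forest$independent.variable.names)
    if (ncol(blocks[[k]]) != need)
      stop(sprintf("block %s width %d does not match training width %d",
                   .blockNames[k], ncol(blocks[[k]]), need))
  }
  P <- vapply(seq_len(4L), function(k) .forestProb(model@forests[[k]], blocks[[k]]),
              numeric(nrow(blocks[[1]])))
  P <- matrix(P, ncol = 4L)
  final <- .sigmoid(model@intercept + as.vector(P %*% model@weights))
  data.frame(p1 = P[, 1], p2 = P[, 2], p3 = P[, 3], p4 = P[, 4],
             final = final)
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA not already positively associated with the disease and
#' returns the top `k` by final stacking score (ties broken by miRNA
#' identifier).
#'
#' @param model a fitted [PMDFIModel-class].
#' @param views list of per-entity code matrices (named FS, SS, GSm, GSd, as
#'   returned by [encodePairFeatures()]), rownames = entity identifiers.
#' @param A the [AssociationMatrix-class] defining known associations.
#' @param disease disease identifier.
#' @param k number of candidates to return (default 10); fewer are returned
#'   when fewer candidates exist.
#' @return data.frame (mirna_id, score) ordered by decreasing score.
#' @export
rankMirnasForDisease <- function(model, views, A, disease, k = 10L) {
  stopifnot(is(A, "AssociationMatrix"))
  if (!disease %in% diseaseIds(A))
    stop(sprintf("unknown disease '%s'", disease))
  if (k < 1) stop("k must be >= 1")
  dj <- match(disease, diseaseIds(A))
  candidates <- which(assocMatrix(A)[, dj] == 0)
  if (!length(candidates))
    return(data.frame(mirna_id = character(), score = numeric()))
  nC <- length(candidates)
  cross <- buildCrossFeatures(
    views$FS[candidates, , drop = FALSE],
    views$SS[rep(dj, nC), , drop = FALSE],
    views$GSm[candidates, , drop = FALSE],
    views$GSd[rep(dj, nC), , drop = FALSE])
  scores <- predictPairs(model, cross)$final
  ids <- mirnaIds(A)[candidates]
  ord <- order(-scores, ids)
  utils::head(data.frame(mirna_id = ids[ord], score = scores[ord],
                         row.names = NULL), k)
}
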