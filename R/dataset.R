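#' Build the adjacency matrix from a confirmed-association list
#'
#' @param pairs data.frame (or 2-column matrix) whose first two columns are
#'   miRNA and disease identifiers of confirmed associations.
#' @param mirnaIds,diseaseIds identifier universes defining the matrix rows
#'   and columns.
#' @return an [AssociationMatrix-class] with a 1 for every listed pair.
#'   Duplicate pairs raise a warning and are counted once; unknown
#'   identifiers are an error.
#' @export
buildAdjacency <- function(pairs, mirnaIds, diseaseIds) {
  pairs <- as.data.frame(pairs)
  A <- matrix(0, length(mirnaIds), length(diseaseIds),
              dimnames = list(mirnaIds, diseaseIds))
  if (nrow(pairs)) {
    mm <- as.character(pairs[[1]]); dd <- as.character(pairs[[2]])
    badM <- unique(mm[!mm %in% mirnaIds])
    badD <- unique(dd[!dd %in% diseaseIds])
    if (length(badM) || length(badD))
      stop(sprintf("unknown identifier(s): %s",
                   paste(c(badM, badD), collapse = ", ")))
    key <- paste(mm, dd, sep = "\r")
    if (anyDuplicated(key)) {
      warning(sprintf("%d duplicate pair(s) counted once", sum(duplicated(key))))
      keep <- !duplicated(key)
      mm <- mm[keep]; dd <- dd[keep]
    }
    A[cbind(mm, dd)] <- 1
  }
  AssociationMatrix(A)
}

#' Enumerate positive or zero pairs of an adjacency matrix
#'
#' @param A an [AssociationMatrix-class].
#' @param value 1 for confirmed (positive) pairs, 0 for unconfirmed pairs.
#' @return data.frame with columns `mirna_index`, `disease_index`, `mirna_id`,
#'   `disease_id`, `label`; rows in column-major matrix order.
#' @export
enumeratePairs <- function(A, value = 1) {
  stopifnot(is(A, "AssociationMatrix"), value %in% c(0, 1))
  idx <- which(assocMatrix(A) == value, arr.ind = TRUE)
  data.frame(
    mirna_index = as.integer(idx[, 1]),
    disease_index = as.integer(idx[, 2]),
    mirna_id = mirnaIds(A)[idx[, 1]],
    disease_id = diseaseIds(A)[idx[, 2]],
    label = as.integer(value),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-pair feature rows for clustering and classification
#'
#' The raw (low-order) representation of a miRNA-disease pair: the miRNA's
#' row of a miRNA-side similarity view concatenated with the disease's row of
#' a disease-side view. The default pairing FS + SS is the clustering space
#' for negative sampling; `views = "all"` concatenates all four views.
#'
#' @param pairs data.frame with `mirna_index` and `disease_index` columns (as
#'   from [enumeratePairs()]).
#' @param FS,SS [SimilarityMatrix-class] views aligned to the adjacency's
#'   miRNA / disease identifiers.
#' @param GSm,GSd optional GIP views, required when `views = "all"`.
#' @param A the [AssociationMatrix-class] the indices refer to, used to check
#'   alignment.
#' @param views "fs_ss" (default) or "all".
#' @return numeric matrix, one row per pair.
#' @export
pairRepresentation <- function(pairs, FS, SS, A, GSm = NULL, GSd = NULL,
                               views = c("fs_ss", "all")) {
  views <- match.arg(views)
  checkAligned <- function(sim, ids, what) {
    if (!identical(entityIds(sim), ids))
      stop(sprintf("%s similarity identifiers are not aligned to the adjacency", what))
  }
  checkAligned(FS, mirnaIds(A), "miRNA functional")
  checkAligned(SS, diseaseIds(A), "disease semantic")
  mi <- pairs$mirna_index; di <- pairs$disease_index
  out <- cbind(simMatrix(FS)[mi, , drop = FALSE],
               simMatrix(SS)[di, , drop = FALSE])
  if (views == "all") {
    if (is.null(GSm) || is.null(GSd))
      stop("views = 'all' requires GSm and GSd")
    checkAligned(GSm, mirnaIds(A), "miRNA GIP")
    checkAligned(GSd, diseaseIds(A), "disease GIP")
    out <- cbind(out, simMatrix(GSm)[mi, , drop = FALSE],
                 simMatrix(GSd)[di, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# k-means++ center selection: first center uniform, each further center drawn
# with probability proportional to squared distance to the nearest chosen one
.kmeansppCenters <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], "-")^2)
  if (k > 1) for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ], "-")^2))
  }
  X[centers, , drop = FALSE]
}

# equal-as-possible quotas: floor(n/k) each, remainder to the largest clusters
.clusterQuotas <- function(sizes, n) {
  k <- length(sizes)
  quota <- rep(n %/% k, k)
  extra <- n - sum(quota)
  if (extra > 0) {
    ord <- order(-sizes, seq_along(sizes))
    quota[ord[seq_len(extra)]] <- quota[ord[seq_len(extra)]] + 1L
  }
  # clusters smaller than their quota hand the deficit to clusters with spare
  # capacity, biggest spare first
  repeat {
    over <- quota > sizes
    if (!any(over)) break
    deficit <- sum(quota[over] - sizes[over])
    quota[over] <- sizes[over]
    spare <- sizes - quota
    if (sum(spare) < deficit)
      stop("not enough zero-pairs to satisfy the requested sample size")
    warning(sprintf("%d draw(s) redistributed from under-sized cluster(s)", deficit))
    ord <- order(-spare, seq_along(spare))
    for (i in ord) {
      take <- min(spare[i], deficit)
      quota[i] <- quota[i] + take
      deficit <- deficit - take
      if (deficit == 0) break
    }
  }
  quota
}

#' Cluster-balanced negative sampling of unconfirmed pairs
#'
#' Unconfirmed (zero) pairs are partitioned into `kClusters` groups by
#' k-means over their feature rows, and an equal-as-possible number of pairs
#' (floor(n/k) each, remainder assigned to the largest clusters) is drawn at
#' random without replacement from each cluster. Balancing the draw across
#' clusters spreads the presumed negatives over the feature space instead of
#' letting one dense region dominate.
#'
#' @param A an [AssociationMatrix-class].
#' @param features numeric matrix with one row per zero-pair of `A`, in
#'   [enumeratePairs()] order (see [pairRepresentation()]).
#' @param kClusters number of k-means clusters (default 23).
#' @param nNegatives number of negatives to draw; default = number of
#'   positive pairs in `A`.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data.frame of sampled zero-pairs as in [enumeratePairs()] (label
#'   0), with the k-means cluster of each drawn pair in column `cluster`.
#' @export
sampleNegatives <- function(A, features, kClusters = 23, nNegatives = NULL,
                            seed = 1) {
  stopifnot(is(A, "AssociationMatrix"))
  zeros <- enumeratePairs(A, value = 0)
  if (nrow(features) != nrow(zeros))
    stop(sprintf("'features' must have one row per zero-pair (%d), got %d",
                 nrow(zeros), nrow(features)))
  nNegatives <- as.integer(nNegatives %||% sum(assocMatrix(A)))
  if (nNegatives < 1 || nNegatives > nrow(zeros))
    stop("nNegatives must be in [1, number of zero-pairs]")
  nDistinct <- nrow(unique(features))
  if (kClusters > nDistinct)
    stop(sprintf("kClusters (%d) exceeds distinct feature points (%d)",
                 kClusters, nDistinct))
  withSeed(seed, {
    cl <- if (kClusters == 1L) rep(1L, nrow(zeros)) else {
      centers <- .kmeansppCenters(features, kClusters)
      stats::kmeans(features, centers = centers, iter.max = 300,
                    algorithm = "Lloyd")$cluster
    }
    sizes <- tabulate(cl, nbins = kClusters)
    quota <- .clusterQuotas(sizes, nNegatives)
    picked <- unlist(lapply(seq_len(kClusters), function(j) {
      members <- which(cl == j)
      if (quota[j] == 0) integer() else members[sample.int(length(members), quota[j])]
    }))
    out <- zeros[sort(picked), , drop = FALSE]
    out$label <- 0L
    out$cluster <- cl[sort(picked)]
    rownames(out) <- NULL
    out
  })
}

#' Assemble the labeled training pairs
#'
#' Positives are every confirmed pair of `A`; negatives come from
#' [sampleNegatives()]. The two sets are disjoint by construction.
#'
#' @inheritParams sampleNegatives
#' @return data.frame of positive and sampled negative pairs with `label`
#'   1/0.
#' @export
buildPairDataset <- function(A, features, kClusters = 23, nNegatives = NULL,
                             seed = 1) {
  pos <- enumeratePairs(A, value = 1)
  neg <- sampleNegatives(A, features, kClusters, nNegatives, seed)
  neg$cluster <- NULL
  rbind(pos, neg)
}
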