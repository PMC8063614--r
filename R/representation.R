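#' Stacked-autoencoder configuration
#'
#' Hyperparameters for greedy layer-wise training. Defaults follow the
#' 256-128-64 hidden-layer architecture, so the high-order feature dimension
#' is 64. Layer widths must be strictly decreasing.
#'
#' @param layerSizes integer vector of hidden-layer widths.
#' @param weightDecay non-negative L2 penalty on weights and biases.
#' @param epochsPerLayer gradient-descent epochs per layer.
#' @param learningRate step size for full-batch gradient descent.
#' @param seed integer seed for weight initialisation.
#' @return a named list of class "saeConfig".
#' @export
saeConfig <- function(layerSizes = c(256L, 128L, 64L), weightDecay = 1e-4,
                      epochsPerLayer = 500L, learningRate = 0.5, seed = 1L) {
  if (length(layerSizes) < 1L || any(diff(layerSizes) >= 0))
    stop("layerSizes must be strictly decreasing")
  if (weightDecay < 0) stop("weightDecay must be non-negative")
  if (epochsPerLayer < 1) stop("epochsPerLayer must be positive")
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(layerSizes = as.integer(layerSizes),
                 weightDecay = weightDecay,
                 epochsPerLayer = as.integer(epochsPerLayer),
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "saeConfig")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Eq-style training objective of one layer: half squared reconstruction error
# summed over samples plus L2 penalty on weights and biases
.saeObjective <- function(X, Y, W1, b1, W2, b2, lambda) {
  0.5 * sum((X - Y)^2) +
    lambda * (sum(W1^2) + sum(W2^2) + sum(b1^2) + sum(b2^2))
}

# train a single autoencoder layer by full-batch gradient descent; gradients
# use the per-sample mean of the reconstruction term so the step size does
# not scale with the number of samples
.trainLayer <- function(X, width, cfg, layerSeed) {
  n <- nrow(X); din <- ncol(X)
  lim1 <- sqrt(6 / (din + width)); lim2 <- sqrt(6 / (width + din))
  withSeed(layerSeed, {
    W1 <- matrix(stats::runif(din * width, -lim1, lim1), din, width)
    W2 <- matrix(stats::runif(width * din, -lim2, lim2), width, din)
  })
  b1 <- numeric(width); b2 <- numeric(din)
  lr <- cfg$learningRate; lambda <- cfg$weightDecay
  lossHistory <- numeric(cfg$epochsPerLayer + 1L)
  G <- .sigmoid(sweep(X %*% W1, 2, b1, "+"))
  Y <- .sigmoid(sweep(G %*% W2, 2, b2, "+"))
  lossHistory[1] <- .saeObjective(X, Y, W1, b1, W2, b2, lambda)
  for (e in seq_len(cfg$epochsPerLayer)) {
    dY <- (Y - X) * Y * (1 - Y)            # n x din
    dG <- (dY %*% t(W2)) * G * (1 - G)     # n x width
    W2 <- W2 - lr * (crossprod(G, dY) / n + 2 * lambda * W2)
    b2 <- b2 - lr * (colMeans(dY) + 2 * lambda * b2)
    W1 <- W1 - lr * (crossprod(X, dG) / n + 2 * lambda * W1)
    b1 <- b1 - lr * (colMeans(dG) + 2 * lambda * b1)
    G <- .sigmoid(sweep(X %*% W1, 2, b1, "+"))
    Y <- .sigmoid(sweep(G %*% W2, 2, b2, "+"))
    lossHistory[e + 1L] <- .saeObjective(X, Y, W1, b1, W2, b2, lambda)
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, lossHistory = lossHistory,
       codes = G)
}

#' Train a greedy layer-wise stacked autoencoder
#'
#' Layer 1 is an autoencoder on the input rows; each later layer is an
#' autoencoder on the previous layer's codes. Each layer minimises the half
#' squared reconstruction error plus an L2 penalty on its parameters by
#' full-batch gradient descent with sigmoid activations on both the encode
#' and decode side (inputs are similarities in [0, 1]). Encoder and decoder
#' weights are untied.
#'
#' @param X numeric matrix of training rows with values in [0, 1] (typically
#'   a similarity matrix: one row per entity).
#' @param cfg an [saeConfig()].
#' @return an [EncoderStack-class]; each layer records its per-epoch training
#'   objective in `lossHistory`.
#' @examples
#' X <- matrix(runif(200), 20, 10)
#' st <- trainSAE(X, saeConfig(layerSizes = c(4L, 2L), epochsPerLayer = 50L))
#' dim(encode(st, X))  # 20 x 2
#' @export
trainSAE <- function(X, cfg = saeConfig()) {
  X <- as.matrix(X)
  if (!nrow(X) || !ncol(X)) stop("input matrix is empty")
  if (any(X < 0) || any(X > 1)) stop("input values must lie in [0, 1]")
  if (!inherits(cfg, "saeConfig")) stop("'cfg' must come from saeConfig()")
  layers <- vector("list", length(cfg$layerSizes))
  cur <- X
  for (i in seq_along(cfg$layerSizes)) {
    layers[[i]] <- .trainLayer(cur, cfg$layerSizes[i], cfg,
                               deriveSeed(cfg$seed, i))
    cur <- layers[[i]]$codes
    layers[[i]]$codes <- NULL
  }
  new("EncoderStack", layers = layers, inputDim = ncol(X),
      config = unclass(cfg))
}

#' @describeIn encode compose the fitted per-layer encoders.
#' @export
setMethod("encode", "EncoderStack", function(object, X) {
  X <- as.matrix(X)
  if (ncol(X) != object@inputDim)
    stop(sprintf("input width %d does not match encoder input width %d",
                 ncol(X), object@inputDim))
  cur <- X
  for (l in object@layers)
    cur <- .sigmoid(sweep(cur %*% l$W1, 2, l$b1, "+"))
  cur
})

#' Build the four cross features from the per-view high-order features
#'
#' Each cross feature concatenates one miRNA-side code (from FS or GSm) with
#' one disease-side code (from SS or GSd), giving the classifier access to
#' pairwise interaction structure:
#' D1 = [FS, SS], D2 = [GSm, SS], D3 = [FS, GSd], D4 = [GSm, GSd].
#'
#' @param Dfs,Dss,Dgsm,Dgsd numeric matrices of per-sample high-order
#'   features (same number of rows; equal widths).
#' @return a [CrossFeatureSet-class]; block width is twice the view width.
#' @export
buildCrossFeatures <- function(Dfs, Dss, Dgsm, Dgsd) {
  mats <- list(Dfs = as.matrix(Dfs), Dss = as.matrix(Dss),
               Dgsm = as.matrix(Dgsm), Dgsd = as.matrix(Dgsd))
  ns <- vapply(mats, nrow, integer(1)); ws <- vapply(mats, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all four views must have the same sample count")
  if (length(unique(ws)) != 1L)
    stop("all four views must have the same width")
  unnamed <- function(m) { dimnames(m) <- NULL; m }
  new("CrossFeatureSet",
      D1 = unnamed(cbind(mats$Dfs, mats$Dss)),
      D2 = unnamed(cbind(mats$Dgsm, mats$Dss)),
      D3 = unnamed(cbind(mats$Dfs, mats$Dgsd)),
      D4 = unnamed(cbind(mats$Dgsm, mats$Dgsd)))
}

#' Encode the four similarity views and build pairwise cross features
#'
#' Convenience wrapper over the representation stage: trains (or reuses) one
#' stacked autoencoder per similarity view on that view's rows, looks up the
#' code of each pair's miRNA and disease, and assembles the
#' [CrossFeatureSet-class].
#'
#' @param pairs data.frame with `mirna_index`, `disease_index`.
#' @param FS,SS,GSm,GSd [SimilarityMatrix-class] views.
#' @param cfg an [saeConfig()]; per-view training seeds are derived from
#'   `cfg$seed`.
#' @param stacks optional pre-trained list of 4 [EncoderStack-class]s (named
#'   FS, SS, GSm, GSd) to reuse.
#' @return list with `cross` (the [CrossFeatureSet-class]), `stacks` (the four
#'   encoder stacks) and `views` (the four per-entity code matrices).
#' @export
encodePairFeatures <- function(pairs, FS, SS, GSm, GSd, cfg = saeConfig(),
                               stacks = NULL) {
  sims <- list(FS = FS, SS = SS, GSm = GSm, GSd = GSd)
  if (is.null(stacks)) {
    stacks <- lapply(seq_along(sims), function(i) {
      c2 <- cfg; c2$seed <- deriveSeed(cfg$seed, 100L + i)
      class(c2) <- "saeConfig"
      trainSAE(simMatrix(sims[[i]]), c2)
    })
    names(stacks) <- names(sims)
  }
  views <- lapply(names(sims), function(nm) {
    codes <- encode(stacks[[nm]], simMatrix(sims[[nm]]))
    rownames(codes) <- entityIds(sims[[nm]])
    codes
  })
  names(views) <- names(sims)
  mi <- pairs$mirna_index; di <- pairs$disease_index
  cross <- buildCrossFeatures(views$FS[mi, , drop = FALSE],
                              views$SS[di, , drop = FALSE],
                              views$GSm[mi, , drop = FALSE],
                              views$GSd[di, , drop = FALSE])
  list(cross = cross, stacks = stacks, views = views)
}
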