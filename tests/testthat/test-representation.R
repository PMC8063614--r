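test_that("a zero-weight encoder maps everything to 0.5", {
  st <- new("EncoderStack",
            layers = list(list(W1 = matrix(0, 3, 2), b1 = numeric(2),
                               W2 = matrix(0, 2, 3), b2 = numeric(3))),
            inputDim = 3L, config = list())
  out <- encode(st, matrix(runif(6), 2, 3))
  expect_equal(as.vector(out), rep(0.5, 4))
})

test_that("a hand-set 1x1 encoder evaluates sigmoid(W x + b)", {
  st <- new("EncoderStack",
            layers = list(list(W1 = matrix(2, 1, 1), b1 = -1,
                               W2 = matrix(1, 1, 1), b2 = 0)),
            inputDim = 1L, config = list())
  expect_equal(as.vector(encode(st, matrix(1))), plogis(1), tolerance = 1e-12)
})

test_that("greedy training reduces each layer's objective on low-rank data", {
  # 50 samples on a 2-d subspace of a 10-d space, squashed into [0, 1]
  set.seed(5)
  basis <- matrix(rnorm(20), 2, 10)
  X <- plogis(matrix(rnorm(100), 50, 2) %*% basis)
  st <- trainSAE(X, saeConfig(layerSizes = 4L, epochsPerLayer = 500L, seed = 1))
  lh <- st@layers[[1]]$lossHistory
  expect_lt(lh[length(lh)], 0.5 * lh[1])
  # objective trend is non-increasing up to small fluctuation
  expect_lt(max(diff(lh)), 1e-6 + 0.01 * lh[1])
  # determinism: same config, same data -> identical stack
  st2 <- trainSAE(X, saeConfig(layerSizes = 4L, epochsPerLayer = 500L, seed = 1))
  expect_identical(st@layers[[1]]$W1, st2@layers[[1]]$W1)
})

test_that("stack wiring: widths chain through the layers and encode is deterministic", {
  set.seed(8)
  X <- matrix(runif(30 * 20), 30, 20)
  st <- trainSAE(X, saeConfig(layerSizes = c(8L, 4L), epochsPerLayer = 30L, seed = 2))
  codes <- encode(st, X)
  expect_equal(dim(codes), c(30L, 4L))
  expect_true(all(codes > 0 & codes < 1))
  expect_identical(codes, encode(st, X))
  # row order does not change per-row codes
  perm <- sample(nrow(X))
  expect_equal(encode(st, X[perm, ]), codes[perm, ], tolerance = 1e-12)
  expect_error(encode(st, X[, 1:7]), "width")
})

test_that("training validates its input domain", {
  expect_error(trainSAE(matrix(numeric(), 0, 3)), "empty")
  expect_error(trainSAE(matrix(c(0.5, 1.2), 1, 2)), "0, 1")
  expect_error(saeConfig(layerSizes = c(64L, 64L)), "decreasing")
})

test_that("stronger weight decay shrinks the learned weight norm", {
  set.seed(9)
  X <- matrix(runif(40 * 10), 40, 10)
  norms <- vapply(c(1e-4, 1e-2, 1), function(lambda) {
    st <- trainSAE(X, saeConfig(layerSizes = 4L, weightDecay = lambda,
                                epochsPerLayer = 200L, seed = 3))
    sqrt(sum(st@layers[[1]]$W1^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("cross features concatenate the right views in the right order", {
  n <- 5; w <- 3
  mk <- function(v) matrix(v, n, w)
  cf <- buildCrossFeatures(mk(1), mk(2), mk(3), mk(4))
  expect_equal(unique(as.vector(crossBlock(cf, "D1"))), c(1, 2))
  expect_equal(unique(as.vector(crossBlock(cf, "D2"))), c(3, 2))
  expect_equal(unique(as.vector(crossBlock(cf, "D3"))), c(1, 4))
  # D4 holds only the two GIP-derived views, never FS/SS sentinels
  expect_equal(unique(as.vector(crossBlock(cf, "D4"))), c(3, 4))
  expect_equal(ncol(crossBlock(cf, "D1")), 2 * w)
  # order within a row: miRNA-side view first
  expect_equal(as.vector(crossBlock(cf, "D1")[1, ]), c(rep(1, w), rep(2, w)))
  expect_error(buildCrossFeatures(mk(1), mk(2), mk(3), matrix(4, n + 1, w)),
               "sample count")
  expect_error(buildCrossFeatures(mk(1), mk(2), mk(3), matrix(4, n, w + 1)),
               "width")
})

test_that("encodePairFeatures yields per-pair codes aligned with entity identity", {
  net <- simulateBlockNetwork(blockNetworkConfig(nMirna = 15, nDisease = 12,
                                                 nBlocks = 3, seed = 2))
  cfg <- blockNetworkConfig(nMirna = 15, nDisease = 12, nBlocks = 3, seed = 2)
  sims <- simulateSimilarities(net$mirnaBlocks, net$diseaseBlocks, cfg)
  GSm <- gipKernel(net$A, "miRNA"); GSd <- gipKernel(net$A, "disease")
  pairs <- data.frame(mirna_index = c(1L, 3L, 1L), disease_index = c(2L, 2L, 5L))
  enc <- encodePairFeatures(pairs, sims$FS, sims$SS, GSm, GSd,
                            saeConfig(layerSizes = c(6L, 3L), epochsPerLayer = 40L,
                                      seed = 1))
  expect_s4_class(enc$cross, "CrossFeatureSet")
  expect_equal(nrow(crossBlock(enc$cross, "D1")), 3)
  # pairs 1 and 3 share the miRNA: identical miRNA-side half of D1
  D1 <- crossBlock(enc$cross, "D1")
  expect_equal(D1[1, 1:3], D1[3, 1:3])
  # pairs 1 and 2 share the disease: identical disease-side half
  expect_equal(D1[1, 4:6], D1[2, 4:6])
})
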