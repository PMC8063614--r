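#' Assemble a pipeline configuration
#'
#' One serialisable object holding every stage's settings; a saved snapshot
#' plus the same inputs reproduces a run exactly because all randomness is
#' derived from the single `seed`.
#'
#' @param inputDir directory with input files (as written by
#'   [writeSyntheticBundle()]); `NULL` to simulate in memory.
#' @param simulate if `TRUE`, generate inputs with the synthetic module.
#' @param network a [blockNetworkConfig()] for simulation.
#' @param sae an [saeConfig()].
#' @param forest a [forestConfig()].
#' @param kClusters,nNegatives negative-sampling settings (see
#'   [sampleNegatives()]); `nNegatives = NULL` matches the positive count.
#' @param folds cross-validation folds.
#' @param stackFolds internal stacking folds.
#' @param threshold classification threshold.
#' @param seed master seed; stage seeds are derived from it.
#' @return named list of class "pipelineConfig".
#' @export
pipelineConfig <- function(inputDir = NULL, simulate = is.null(inputDir),
                           network = blockNetworkConfig(),
                           sae = saeConfig(), forest = forestConfig(),
                           kClusters = 23L, nNegatives = NULL, folds = 5L,
                           stackFolds = 5L, threshold = 0.5, seed = 1L) {
  structure(list(inputDir = inputDir, simulate = simulate, network = network,
                 sae = sae, forest = forest, kClusters = as.integer(kClusters),
                 nNegatives = nNegatives, folds = as.integer(folds),
                 stackFolds = as.integer(stackFolds), threshold = threshold,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

# load the input bundle written by writeSyntheticBundle (or hand-prepared in
# the same formats)
.loadInputs <- function(dir) {
  mirna <- readLines(file.path(dir, "mirna_ids.txt"))
  disease <- readLines(file.path(dir, "disease_ids.txt"))
  pairs <- utils::read.delim(file.path(dir, "associations.tsv"),
                             header = FALSE, colClasses = "character")
  A <- buildAdjacency(pairs, mirna, disease)
  FS <- loadSimilarityTable(file.path(dir, "fs.tsv"), mirna, "FS")
  ssPath <- file.path(dir, "ss.tsv")
  SS <- if (file.exists(ssPath)) loadSimilarityTable(ssPath, disease, "SS")
  else semanticSimilarity(readDiseaseDAG(file.path(dir, "dag_edges.tsv"),
                                         file.path(dir, "dag_annotation.tsv")),
                          disease)
  list(A = A, FS = FS, SS = SS)
}

#' Run the full prediction pipeline
#'
#' Executes the four stages in order: (1) data — load or simulate the
#' association matrix and FS/SS similarities, compute both GIP kernels,
#' enumerate positives and draw cluster-balanced negatives; (2) high-order
#' features — train one stacked autoencoder per similarity view; (3)
#' interaction — build the four cross features per sampled pair; (4)
#' ensemble — stratified cross-validation of the stacking model. When
#' `outDir` is given, metrics, per-pair scores and a config snapshot are
#' written there.
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory.
#' @return list: `cv` (the [crossValidate()] result), `dataset` (labeled
#'   pairs), `model` (a [PMDFIModel-class] refit on all sampled pairs),
#'   `cross` (the [CrossFeatureSet-class] of the sampled pairs), `views`
#'   (per-entity codes), `inputs` (A, FS, SS, GSm, GSd).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  seed <- config$seed
  # stage 1: data
  if (config$simulate) {
    net <- simulateBlockNetwork(config$network)
    sims <- simulateSimilarities(net$mirnaBlocks, net$diseaseBlocks,
                                 config$network)
    A <- net$A; FS <- sims$FS; SS <- sims$SS
  } else {
    inp <- .loadInputs(config$inputDir)
    A <- inp$A; FS <- inp$FS; SS <- inp$SS
  }
  GSm <- gipKernel(A, "miRNA")
  GSd <- gipKernel(A, "disease")
  zeros <- enumeratePairs(A, 0)
  zeroFeat <- pairRepresentation(zeros, FS, SS, A)
  dataset <- buildPairDataset(A, zeroFeat, config$kClusters,
                              config$nNegatives, deriveSeed(seed, 5L))
  # stages 2-3: high-order features and cross features
  saeCfg <- config$sae; saeCfg$seed <- deriveSeed(seed, 6L)
  class(saeCfg) <- "saeConfig"
  enc <- encodePairFeatures(dataset, FS, SS, GSm, GSd, saeCfg)
  # stage 4: ensemble evaluation + final model on all sampled pairs
  cv <- crossValidate(enc$cross, dataset$label, config$folds,
                      deriveSeed(seed, 7L), config$forest,
                      config$stackFolds, config$threshold)
  model <- fitPMDFI(enc$cross, dataset$label, config$forest,
                    config$stackFolds, deriveSeed(seed, 8L))
  res <- list(cv = cv, dataset = dataset, model = model, cross = enc$cross,
              views = enc$views,
              inputs = list(A = A, FS = FS, SS = SS, GSm = GSm, GSd = GSd))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      cbind(fold = seq_len(nrow(cv$perFold)), round(cv$perFold, 6)),
      file.path(outDir, "cv_metrics.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    scored <- cbind(dataset[, c("mirna_id", "disease_id", "label")],
                    predictPairs(model, enc$cross))
    utils::write.table(scored, file.path(outDir, "pair_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    snapshot <- unclass(config)
    for (nm in c("network", "sae", "forest")) snapshot[[nm]] <- unclass(snapshot[[nm]])
    jsonlite::write_json(
      list(mean = as.list(round(cv$mean, 6)),
           perFold = cv$perFold,
           config = snapshot),
      file.path(outDir, "cv_result.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  res
}
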