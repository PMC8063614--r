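#' Block-network configuration for synthetic benchmarks
#'
#' The generator plants a block (community) structure: miRNAs and diseases
#' are assigned to blocks, and associations are much more likely within a
#' block than between blocks. This emulates the structural assumption the
#' predictor relies on — functionally similar miRNAs share diseases —
#' without requiring any external database.
#'
#' @param nMirna,nDisease entity counts (defaults 100, 80).
#' @param nBlocks number of planted blocks (default 5).
#' @param pIn,pOut association probability within / between blocks
#'   (defaults 0.30, 0.02).
#' @param simNoise standard deviation multiplier of the similarity noise
#'   (default 0.1).
#' @param seed integer seed.
#' @return named list of class "blockNetworkConfig".
#' @export
blockNetworkConfig <- function(nMirna = 100L, nDisease = 80L, nBlocks = 5L,
                               pIn = 0.30, pOut = 0.02, simNoise = 0.1,
                               seed = 1L) {
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("require 0 <= pOut < pIn <= 1")
  if (nBlocks > min(nMirna, nDisease))
    stop("nBlocks must not exceed min(nMirna, nDisease)")
  if (simNoise < 0) stop("simNoise must be non-negative")
  structure(list(nMirna = as.integer(nMirna), nDisease = as.integer(nDisease),
                 nBlocks = as.integer(nBlocks), pIn = pIn, pOut = pOut,
                 simNoise = simNoise, seed = as.integer(seed)),
            class = "blockNetworkConfig")
}

#' Simulate a block-structured bipartite association network
#'
#' Entities are assigned to blocks in balanced random fashion; each
#' miRNA-disease pair is associated with probability `pIn` when the two
#' share a block and `pOut` otherwise.
#'
#' @param cfg a [blockNetworkConfig()].
#' @return list: `A` ([AssociationMatrix-class]), `mirnaBlocks`,
#'   `diseaseBlocks` (integer block memberships).
#' @export
simulateBlockNetwork <- function(cfg = blockNetworkConfig()) {
  stopifnot(inherits(cfg, "blockNetworkConfig"))
  withSeed(cfg$seed, {
    mb <- sample(rep_len(seq_len(cfg$nBlocks), cfg$nMirna))
    db <- sample(rep_len(seq_len(cfg$nBlocks), cfg$nDisease))
    same <- outer(mb, db, "==")
    p <- ifelse(same, cfg$pIn, cfg$pOut)
    A <- matrix(as.numeric(stats::runif(length(p)) < p), cfg$nMirna,
                cfg$nDisease,
                dimnames = list(sprintf("mir-%03d", seq_len(cfg$nMirna)),
                                sprintf("dis-%03d", seq_len(cfg$nDisease))))
    list(A = AssociationMatrix(A),
         mirnaBlocks = stats::setNames(mb, rownames(A)),
         diseaseBlocks = stats::setNames(db, colnames(A)))
  })
}

# one surrogate similarity matrix over entities with block memberships:
# same-block pairs centred at baseIn, others at baseOut, symmetric by
# construction, unit diagonal, clamped to [0, 1]
.blockSimilarity <- function(blocks, baseIn, baseOut, noise, ids) {
  n <- length(blocks)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    ut <- upper.tri(S)
    same <- outer(blocks, blocks, "==")[ut]
    eps <- stats::rnorm(sum(ut))
    vals <- ifelse(same, baseIn - noise * eps, baseOut + noise * eps)
    S[ut] <- pmin(pmax(vals, 0), 1)
    S <- S + t(S)
  }
  diag(S) <- 1
  S
}

#' Simulate surrogate similarity matrices from block memberships
#'
#' Stands in for the functional (FS) and semantic (SS) similarity inputs:
#' same-block pairs are similar (base 0.8), different-block pairs dissimilar
#' (base 0.1), with Gaussian noise of scale `simNoise`, clamped to [0, 1].
#' With `signal = FALSE` both bases collapse to 0.45, producing pure-noise
#' similarities for negative-control (null calibration) runs.
#'
#' @param mirnaBlocks,diseaseBlocks named block memberships from
#'   [simulateBlockNetwork()].
#' @param cfg a [blockNetworkConfig()].
#' @param signal if `FALSE`, similarities carry no block information.
#' @return list with [SimilarityMatrix-class] elements `FS` and `SS`.
#' @export
simulateSimilarities <- function(mirnaBlocks, diseaseBlocks,
                                 cfg = blockNetworkConfig(), signal = TRUE) {
  baseIn <- if (signal) 0.8 else 0.45
  baseOut <- if (signal) 0.1 else 0.45
  withSeed(deriveSeed(cfg$seed, 2L), {
    fs <- .blockSimilarity(mirnaBlocks, baseIn, baseOut, cfg$simNoise,
                           names(mirnaBlocks))
    ss <- .blockSimilarity(diseaseBlocks, baseIn, baseOut, cfg$simNoise,
                           names(diseaseBlocks))
    list(FS = SimilarityMatrix(fs, "FS"), SS = SimilarityMatrix(ss, "SS"))
  })
}

#' Simulate a toy disease-term forest
#'
#' Builds a forest of rooted trees (each internal node has `branching`
#' children down to `maxDepth` levels) and annotates each disease to one
#' leaf, cycling over trees so that leaves are spread as evenly as possible.
#' With `maxDepth = 1` every tree is a bare root and every disease is
#' annotated to a root; with `branching = 1` each tree is a chain.
#'
#' @param nDiseases number of diseases to annotate.
#' @param maxDepth tree depth in levels (root = level 1).
#' @param branching children per internal node.
#' @param seed integer seed (leaf assignment).
#' @return a [DiseaseDAG-class] with diseases "dis-001", ...
#' @export
simulateDagForest <- function(nDiseases, maxDepth = 3L, branching = 2L,
                              seed = 1L) {
  if (nDiseases < 1 || maxDepth < 1 || branching < 1)
    stop("parameters must be positive")
  leavesPerTree <- branching^(maxDepth - 1L)
  nTrees <- max(1L, ceiling(nDiseases / leavesPerTree))
  nodes <- character(); parents <- list(); leaves <- character()
  for (tr in seq_len(nTrees)) {
    level <- sprintf("t%d_r", tr)  # root
    nodes <- c(nodes, level)
    for (d in seq_len(maxDepth - 1L)) {
      children <- unlist(lapply(level, function(p)
        sprintf("%s_%d", p, seq_len(branching))))
      for (i in seq_along(children))
        parents[[children[i]]] <- level[ceiling(i / branching)]
      nodes <- c(nodes, children)
      level <- children
    }
    leaves <- c(leaves, level)
  }
  withSeed(seed, {
    assignLeaf <- rep_len(sample(leaves), nDiseases)
    ann <- stats::setNames(as.list(assignLeaf),
                           sprintf("dis-%03d", seq_len(nDiseases)))
    DiseaseDAG(nodes, parents = parents, annotation = ann)
  })
}

#' Write the full synthetic input bundle to a directory
#'
#' Generates the association network and surrogate similarities and writes
#' them in the loader formats: association pair list TSV, identifier
#' universe files, labeled FS/SS similarity TSVs, DAG edge/annotation TSVs,
#' and a JSON file with the ground-truth block memberships.
#'
#' @param dir output directory (created if missing).
#' @param cfg a [blockNetworkConfig()].
#' @return invisible list of the generated objects.
#' @export
writeSyntheticBundle <- function(dir, cfg = blockNetworkConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- simulateBlockNetwork(cfg)
  sims <- simulateSimilarities(net$mirnaBlocks, net$diseaseBlocks, cfg)
  dag <- simulateDagForest(cfg$nDisease, seed = deriveSeed(cfg$seed, 3L))
  pos <- enumeratePairs(net$A, 1)
  utils::write.table(pos[, c("mirna_id", "disease_id")],
                     file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(mirnaIds(net$A), file.path(dir, "mirna_ids.txt"))
  writeLines(diseaseIds(net$A), file.path(dir, "disease_ids.txt"))
  writeSimilarityTable(sims$FS, file.path(dir, "fs.tsv"))
  writeSimilarityTable(sims$SS, file.path(dir, "ss.tsv"))
  edges <- do.call(rbind, lapply(names(dag@parents), function(ch)
    if (length(dag@parents[[ch]])) data.frame(child = ch, parent = dag@parents[[ch]])))
  utils::write.table(edges, file.path(dir, "dag_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ann <- data.frame(disease = rep(names(dag@annotation), lengths(dag@annotation)),
                    node = unlist(dag@annotation, use.names = FALSE))
  utils::write.table(ann, file.path(dir, "dag_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(mirnaBlocks = as.list(net$mirnaBlocks),
         diseaseBlocks = as.list(net$diseaseBlocks),
         config = unclass(cfg)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(list(net = net, sims = sims, dag = dag))
}
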