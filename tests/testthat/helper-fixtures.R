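# fixture builders shared across test files; everything is generated in code

tinyAdjacency <- function() {
  AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
                           dimnames = list(c("m1", "m2"), c("d1", "d2"))))
}

# three-term chain G -> P -> D with diseases annotated at D and P
chainDag <- function() {
  DiseaseDAG(c("G", "P", "D"), parents = list(D = "P", P = "G"),
             annotation = list(dD = "D", dP = "P"))
}

# independent brute-force disease semantic similarity: fixpoint iteration for
# contributions, explicit enumeration of the shared ancestor set
bruteContribution <- function(dag, node) {
  # ancestor closure by repeated expansion
  terms <- node
  repeat {
    more <- unique(unlist(lapply(terms, function(t) dag@parents[[t]])))
    new <- setdiff(more, terms)
    if (!length(new)) break
    terms <- c(terms, new)
  }
  contrib <- stats::setNames(rep(-Inf, length(terms)), terms)
  contrib[node] <- 1
  repeat {
    old <- contrib
    for (t in terms) {
      if (t == node) next
      kids <- terms[vapply(terms, function(c) t %in% dag@parents[[c]], logical(1))]
      if (length(kids)) contrib[t] <- 0.5 * max(contrib[kids])
    }
    if (identical(old, contrib)) break
  }
  contrib
}

bruteSemanticSim <- function(dag, d1, d2) {
  c1 <- Reduce(function(a, b) {
    all <- union(names(a), names(b))
    stats::setNames(pmax(a[all], b[all], na.rm = TRUE), all)
  }, lapply(dag@annotation[[d1]], function(n) bruteContribution(dag, n)))
  c2 <- Reduce(function(a, b) {
    all <- union(names(a), names(b))
    stats::setNames(pmax(a[all], b[all], na.rm = TRUE), all)
  }, lapply(dag@annotation[[d2]], function(n) bruteContribution(dag, n)))
  shared <- intersect(names(c1), names(c2))
  if (!length(shared)) return(0)
  sum(c1[shared] + c2[shared]) / (sum(c1) + sum(c2))
}

# random DAG on <= nMax nodes: edges only from later to earlier nodes in a
# fixed order, so acyclicity holds by construction
randomSmallDag <- function(nMax = 6, seed = 1) {
  set.seed(seed)
  n <- sample(2:nMax, 1)
  nodes <- paste0("t", seq_len(n))
  parents <- list()
  for (i in 2:n) {
    nPar <- sample(0:min(2, i - 1), 1)
    if (nPar > 0)
      parents[[nodes[i]]] <- sample(nodes[seq_len(i - 1)], nPar)
  }
  ann <- list(dA = sample(nodes, 1), dB = sample(nodes, 1))
  DiseaseDAG(nodes, parents = parents, annotation = ann)
}

# brute-force AUC: pairwise concordance over all positive-negative pairs
bruteAUC <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small but non-trivial synthetic problem for ensemble/evaluation unit tests:
# planted two-block structure with clearly separated classes
smallCrossFixture <- function(n = 120, width = 8, seed = 42) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  mk <- function(shift) {
    m <- matrix(stats::rnorm(n * width, sd = 0.3), n, width)
    m[labels == 1, ] <- m[labels == 1, ] + shift
    m
  }
  cross <- buildCrossFeatures(mk(1), mk(1), mk(1), mk(1))
  list(cross = cross, labels = labels)
}

# default-condition pipeline runs are expensive; compute once per session and
# share across test blocks
.pipelineCache <- new.env(parent = emptyenv())

defaultPipelineRun <- function() {
  if (is.null(.pipelineCache$run))
    .pipelineCache$run <- suppressWarnings(runPipeline(pipelineConfig(seed = 1)))
  .pipelineCache$run
}
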