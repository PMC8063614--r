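test_that("GIP kernel matches the hand-evaluated 2x2 oracle on both axes", {
  A <- tinyAdjacency()
  for (axis in c("miRNA", "disease")) {
    K <- gipKernel(A, axis)
    m <- simMatrix(K)
    # gamma = 1 / ((1 + 1) / 2) = 1, squared profile distance = 2
    expect_equal(m[1, 2], exp(-2), tolerance = 1e-12)
    expect_equal(diag(m), c(1, 1), ignore_attr = TRUE)
    expect_identical(m, t(m))
    expect_identical(simKind(K), if (axis == "miRNA") "GSm" else "GSd")
  }
})

test_that("GIP kernel properties: identical profiles, bandwidth identity, permutation", {
  set.seed(7)
  A <- matrix(rbinom(60, 1, 0.4), 6, 10,
              dimnames = list(paste0("m", 1:6), paste0("d", 1:10)))
  A[2, ] <- A[1, ]  # duplicate profile
  Am <- AssociationMatrix(A)
  K <- simMatrix(gipKernel(Am, "miRNA"))
  expect_equal(K[1, 2], 1)
  # gamma * mean squared norm == lambda exactly
  gamma <- -log(K[1, 3]) / sum((A[1, ] - A[3, ])^2)
  expect_equal(gamma * mean(rowSums(A^2)), 1, tolerance = 1e-9)
  # permuting the non-axis dimension leaves the kernel unchanged
  perm <- sample(ncol(A))
  Kp <- simMatrix(gipKernel(AssociationMatrix(A[, perm]), "miRNA"))
  expect_equal(K, Kp, tolerance = 1e-12)
  # lambda scales the bandwidth
  K2 <- simMatrix(gipKernel(Am, "miRNA", lambda = 2))
  expect_equal(K2[1, 3], K[1, 3]^2, tolerance = 1e-12)
})

test_that("GIP kernel rejects all-zero adjacency and bad axis", {
  Z <- AssociationMatrix(matrix(0, 2, 2,
    dimnames = list(c("m1", "m2"), c("d1", "d2"))))
  expect_error(gipKernel(Z, "miRNA"), "miRNA")
  expect_error(gipKernel(Z, "disease"), "disease")
  expect_error(gipKernel(tinyAdjacency(), "gene"))
})

test_that("DAG contributions follow the 0.5-decay recursion with max semantics", {
  dag <- chainDag()
  expect_equal(dagContribution(dag, "dD"),
               c(D = 1, P = 0.5, G = 0.25), ignore_attr = TRUE)
  expect_equal(semanticValue(dag, "dD"), 1.75)
  # isolated root
  root <- DiseaseDAG("R", annotation = list(x = "R"))
  expect_equal(dagContribution(root, "x"), c(R = 1), ignore_attr = TRUE)
  expect_equal(semanticValue(root, "x"), 1)
  # diamond: two parents both children of G -> G takes the max, not the sum
  dia <- DiseaseDAG(c("G", "P1", "P2", "D"),
                    parents = list(D = c("P1", "P2"), P1 = "G", P2 = "G"),
                    annotation = list(x = "D"))
  co <- dagContribution(dia, "x")
  expect_equal(co[["G"]], 0.25)
  expect_equal(semanticValue(dia, "x"), 2.25)
  expect_error(dagContribution(dag, "nope"), "not annotated")
})

test_that("semantic similarity matches the chain oracle and basic contracts", {
  dag <- chainDag()
  S <- simMatrix(semanticSimilarity(dag, c("dD", "dP")))
  expect_equal(S["dD", "dP"], 2.25 / 3.25, tolerance = 1e-12)
  expect_equal(diag(S), c(1, 1), ignore_attr = TRUE)
  # disjoint trees share no ancestors
  two <- DiseaseDAG(c("A", "B"), annotation = list(x = "A", y = "B"))
  expect_equal(simMatrix(semanticSimilarity(two, c("x", "y")))["x", "y"], 0)
  expect_error(semanticSimilarity(dag, c("dD", "ghost")), "ghost")
})

test_that("semantic similarity agrees with the brute-force enumerator on random small DAGs", {
  for (s in 1:40) {
    dag <- randomSmallDag(6, seed = s)
    S <- simMatrix(semanticSimilarity(dag, c("dA", "dB")))
    expect_equal(S["dA", "dB"], bruteSemanticSim(dag, "dA", "dB"),
                 tolerance = 1e-12,
                 info = sprintf("random DAG seed %d", s))
  }
})

test_that("multi-position annotation takes union of ancestors with max contribution", {
  dag <- DiseaseDAG(c("R", "A", "B", "C"),
                    parents = list(A = "R", B = "R", C = "B"),
                    annotation = list(x = c("A", "C"), y = "B"))
  co <- dagContribution(dag, "x")
  expect_setequal(names(co), c("A", "C", "B", "R"))
  # R is a direct parent of A (0.5) and grandparent via C (0.25): max wins
  expect_equal(co[["R"]], 0.5)
})

test_that("similarity table loader validates, realigns, and names offenders", {
  ids <- c("a", "b", "c")
  m <- diag(3); dimnames(m) <- list(ids, ids)
  f <- tempfile(fileext = ".tsv")
  writeSimilarityTable(SimilarityMatrix(m, "FS"), f)
  got <- loadSimilarityTable(f, ids)
  expect_equal(simMatrix(got), m)
  # permuted row order is realigned to expected ids
  perm <- m[c(3, 1, 2), c(2, 3, 1)]
  df <- data.frame(id = rownames(perm), perm, check.names = FALSE)
  colnames(df) <- c("id", colnames(perm))
  f2 <- tempfile(fileext = ".tsv")
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(simMatrix(loadSimilarityTable(f2, ids)), m)
  # out-of-range entry is rejected with the offending cell named
  bad <- m; bad["a", "b"] <- 1.2; bad["b", "a"] <- 1.2
  dfb <- data.frame(id = ids, bad, check.names = FALSE)
  colnames(dfb) <- c("id", ids)
  f3 <- tempfile(fileext = ".tsv")
  write.table(dfb, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadSimilarityTable(f3, ids), "\\[a, b\\]")
  # missing identifier
  expect_error(loadSimilarityTable(f, c(ids, "zz")), "zz")
})

test_that("SimilarityMatrix validity enforces symmetry, range and diagonal", {
  m <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s4_class(SimilarityMatrix(m, "SS"), "SimilarityMatrix")
  bad <- m; bad[1, 2] <- 0.9
  expect_error(SimilarityMatrix(bad, "SS"), "symmetric")
  neg <- m; neg[1, 2] <- neg[2, 1] <- -0.1
  expect_error(SimilarityMatrix(neg, "SS"), "0, 1")
  offdiag <- m; diag(offdiag) <- 0.5
  expect_error(SimilarityMatrix(offdiag, "SS"), "diagonal")
  # FS kind does not require a unit diagonal
  expect_s4_class(SimilarityMatrix(offdiag, "FS"), "SimilarityMatrix")
})

test_that("DiseaseDAG validity rejects cycles and dangling references", {
  expect_error(DiseaseDAG(c("A", "B"), parents = list(A = "B", B = "A"),
                          annotation = list(x = "A")), "cycle")
  expect_error(DiseaseDAG("A", annotation = list(x = "Z")), "unknown")
})

test_that("DAG round-trips through the edge-list/annotation file format", {
  dag <- chainDag()
  ed <- tempfile(); an <- tempfile()
  write.table(data.frame(c("D", "P"), c("P", "G")), ed, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(c("dD", "dP"), c("D", "P")), an, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  got <- readDiseaseDAG(ed, an)
  expect_equal(semanticValue(got, "dD"), 1.75)
  S <- simMatrix(semanticSimilarity(got, c("dD", "dP")))
  expect_equal(S["dD", "dP"], 2.25 / 3.25, tolerance = 1e-12)
})
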