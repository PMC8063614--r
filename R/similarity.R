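#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Radial-basis similarity between the binary interaction profiles of two
#' entities in the bipartite association network. For miRNAs the profile of
#' m_i is row i of the adjacency matrix (its associations over all diseases);
#' for diseases the profile of d_j is column j (its associations over all
#' miRNAs). The kernel is
#' \deqn{GS(u, v) = \exp(-\gamma \, \|IP(u) - IP(v)\|^2)}
#' with bandwidth \eqn{\gamma = \lambda' / \mathrm{mean}_i \|IP(i)\|^2}
#' normalised by the mean squared profile norm, \eqn{\lambda' = 1} by default.
#'
#' @param A an [AssociationMatrix-class].
#' @param axis `"miRNA"` (profiles = rows) or `"disease"` (profiles =
#'   columns).
#' @param lambda positive bandwidth multiplier \eqn{\lambda'} (default 1).
#' @return a [SimilarityMatrix-class] of kind "GSm" (miRNA axis) or "GSd"
#'   (disease axis): symmetric, unit diagonal, entries in (0, 1].
#' @examples
#' A <- AssociationMatrix(diag(2) * 1 + 0)  # needs dimnames:
#' A <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' simMatrix(gipKernel(A, "miRNA"))["m1", "m2"]  # exp(-2)
#' @export
gipKernel <- function(A, axis = c("miRNA", "disease"), lambda = 1) {
  stopifnot(is(A, "AssociationMatrix"))
  axis <- match.arg(axis)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("'lambda' must be a positive scalar")
  P <- if (axis == "miRNA") assocMatrix(A) else t(assocMatrix(A))
  sq <- rowSums(P^2)
  if (all(sq == 0))
    stop(sprintf("all %s interaction profiles are zero: GIP bandwidth undefined", axis))
  gamma <- lambda / mean(sq)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  diag(K) <- 1
  SimilarityMatrix(K, kind = if (axis == "miRNA") "GSm" else "GSd")
}

# ancestors of `node` under the child -> parent relation, excluding the node
.ancestors <- function(dag, node) {
  seen <- character()
  frontier <- dag@parents[[node]] %||% character()
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag@parents[new], use.names = FALSE)) %||% character()
  }
  seen
}

# contribution map of a single annotated node: the node scores 1 and each
# ancestor scores decay * max over its children inside the ancestor closure
.nodeContribution <- function(dag, node) {
  terms <- c(node, .ancestors(dag, node))
  inT <- stats::setNames(rep(TRUE, length(terms)), terms)
  # children restricted to the closure
  childrenOf <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    for (p in dag@parents[[t]]) {
      if (!is.null(inT[p]) && !is.na(inT[p]))
        childrenOf[[p]] <- c(childrenOf[[p]], t)
    }
  }
  contrib <- stats::setNames(rep(NA_real_, length(terms)), terms)
  budget <- length(terms) + 1L
  compute <- function(t, depth) {
    if (depth > budget) stop("cycle detected while computing DAG contributions")
    if (!is.na(contrib[[t]])) return(contrib[[t]])
    val <- if (t == node) 1 else {
      kids <- childrenOf[[t]]
      dag@decay * max(vapply(kids, compute, numeric(1), depth = depth + 1L))
    }
    contrib[[t]] <<- val
    val
  }
  for (t in terms) compute(t, 0L)
  contrib
}

#' Semantic contribution of DAG terms to a disease
#'
#' For a disease D annotated to term(s) of the DAG, every term in T(D) — the
#' annotated terms plus all their ancestors — contributes to D's semantics:
#' an annotated term contributes 1, and each ancestor contributes the maximum
#' over its children within T(D) of 0.5 times the child's contribution.
#' Diseases annotated to several DAG positions take the union of ancestor
#' closures with the elementwise maximum contribution.
#'
#' @param dag a [DiseaseDAG-class].
#' @param disease disease identifier annotated in `dag`.
#' @return named numeric vector: contribution of every term in T(D), values
#'   in (0, 1].
#' @examples
#' dag <- DiseaseDAG(c("G", "P", "D"), parents = list(D = "P", P = "G"),
#'   annotation = list(x = "D"))
#' dagContribution(dag, "x")  # D = 1, P = 0.5, G = 0.25
#' @export
dagContribution <- function(dag, disease) {
  stopifnot(is(dag, "DiseaseDAG"))
  ann <- dag@annotation[[disease]]
  if (is.null(ann))
    stop(sprintf("disease '%s' is not annotated in the DAG", disease))
  maps <- lapply(ann, function(node) .nodeContribution(dag, node))
  allTerms <- unique(unlist(lapply(maps, names)))
  out <- stats::setNames(rep(0, length(allTerms)), allTerms)
  for (m in maps) out[names(m)] <- pmax(out[names(m)], m)
  out
}

#' Semantic value of a disease
#'
#' The semantic value DV(D) is the sum of the contributions of all terms in
#' T(D); it is at least 1 (the annotated term itself) and grows with the
#' depth of the disease in the term hierarchy.
#'
#' @inheritParams dagContribution
#' @return numeric scalar >= 1.
#' @export
semanticValue <- function(dag, disease) {
  sum(dagContribution(dag, disease))
}

#' DAG-based disease semantic similarity
#'
#' Pairwise similarity of diseases from their positions in the term DAG:
#' \deqn{SS(i, j) = \frac{\sum_{t \in T(i) \cap T(j)} (D_i(t) + D_j(t))}
#'   {DV(i) + DV(j)}}
#' where D_i(t) is the contribution of shared term t to disease i and DV the
#' semantic value. Diseases sharing no terms score 0; self-similarity is
#' exactly 1.
#'
#' @param dag a [DiseaseDAG-class].
#' @param diseases character vector of disease identifiers; all must be
#'   annotated.
#' @return a [SimilarityMatrix-class] of kind "SS" over `diseases`.
#' @export
semanticSimilarity <- function(dag, diseases) {
  stopifnot(is(dag, "DiseaseDAG"))
  diseases <- as.character(diseases)
  missing <- diseases[!diseases %in% names(dag@annotation)]
  if (length(missing))
    stop(sprintf("unannotated disease(s): %s", paste(unique(missing), collapse = ", ")))
  maps <- lapply(diseases, function(d) dagContribution(dag, d))
  dv <- vapply(maps, sum, numeric(1))
  n <- length(diseases)
  S <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    S[i, i] <- 1
    if (i < n) for (j in seq((i + 1), n)) {
      shared <- intersect(names(maps[[i]]), names(maps[[j]]))
      s <- if (length(shared))
        sum(maps[[i]][shared] + maps[[j]][shared]) / (dv[i] + dv[j]) else 0
      S[i, j] <- S[j, i] <- s
    }
  }
  SimilarityMatrix(S, kind = "SS")
}

#' Read a disease DAG from edge-list and annotation tables
#'
#' Two tab-separated inputs: an edge list with columns (child_id, parent_id)
#' and an annotation table with columns (disease_id, node_id). Multiple rows
#' per disease annotate it to multiple DAG positions.
#'
#' @param edgeFile path to the child/parent edge list TSV (no header).
#' @param annotationFile path to the disease/node annotation TSV (no header).
#' @return a [DiseaseDAG-class].
#' @export
readDiseaseDAG <- function(edgeFile, annotationFile) {
  edges <- utils::read.delim(edgeFile, header = FALSE,
                             colClasses = "character", col.names = c("child", "parent"))
  ann <- utils::read.delim(annotationFile, header = FALSE,
                           colClasses = "character", col.names = c("disease", "node"))
  nodes <- unique(c(edges$child, edges$parent, ann$node))
  parents <- split(edges$parent, factor(edges$child, levels = nodes))
  parents <- parents[lengths(parents) > 0]
  DiseaseDAG(nodes, parents = parents,
             annotation = split(ann$node, ann$disease))
}

#' Load a precomputed similarity matrix from a labeled table
#'
#' Reads a labeled TSV/CSV similarity table (first column and header row hold
#' the identifiers), validates that it covers `expectedIds`, realigns rows
#' and columns to that ordering, and enforces the similarity invariants
#' (symmetry, range). The main use is the downloaded miRNA functional
#' similarity (MISIM) matrix, which this package consumes but never computes.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) table.
#' @param expectedIds character vector: identifiers the matrix must cover, in
#'   the order the caller's adjacency uses.
#' @param kind similarity view label, default "FS".
#' @return a [SimilarityMatrix-class] aligned to `expectedIds`.
#' @export
loadSimilarityTable <- function(path, expectedIds, kind = "FS") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!setequal(rownames(m), colnames(m)))
    stop("row and column identifier sets differ")
  missing <- setdiff(expectedIds, rownames(m))
  if (length(missing))
    stop(sprintf("similarity table is missing identifiers: %s",
                 paste(missing, collapse = ", ")))
  m <- m[expectedIds, expectedIds, drop = FALSE]
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    cells <- apply(bad[seq_len(min(5, nrow(bad))), , drop = FALSE], 1, function(ij)
      sprintf("[%s, %s] = %g", rownames(m)[ij[1]], colnames(m)[ij[2]], m[ij[1], ij[2]]))
    stop(sprintf("similarity values outside [0, 1]: %s", paste(cells, collapse = "; ")))
  }
  if (asymmetry(m) > 1e-10) {
    ij <- which(abs(m - t(m)) == asymmetry(m), arr.ind = TRUE)[1, ]
    stop(sprintf("table asymmetric beyond tolerance at [%s, %s]",
                 rownames(m)[ij[1]], colnames(m)[ij[2]]))
  }
  SimilarityMatrix(m, kind = kind)
}

#' Write a SimilarityMatrix as a labeled TSV
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimilarityTable <- function(sim, path) {
  stopifnot(is(sim, "SimilarityMatrix"))
  df <- data.frame(id = entityIds(sim), simMatrix(sim), check.names = FALSE)
  colnames(df) <- c("id", entityIds(sim))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
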