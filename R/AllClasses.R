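#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' AssociationMatrix: binary miRNA x disease adjacency
#'
#' Container for the experimentally confirmed association network: a binary
#' matrix A with one row per miRNA and one column per disease, A(i,j) = 1 when
#' the pair is a confirmed association. Row i is the interaction profile of
#' miRNA i over all diseases; column j is the interaction profile of disease j
#' over all miRNAs.
#'
#' @slot assoc binary numeric matrix with unique rownames (miRNA identifiers)
#'   and colnames (disease identifiers).
#' @seealso [buildAdjacency()], [gipKernel()]
#' @exportClass AssociationMatrix
setClass("AssociationMatrix", representation(assoc = "matrix"))

setValidity("AssociationMatrix", function(object) {
  m <- object@assoc
  msgs <- character()
  if (!isBinaryMatrix(m))
    msgs <- c(msgs, "all entries must be exactly 0 or 1")
  rn <- rownames(m); cn <- colnames(m)
  if (is.null(rn) || is.null(cn))
    msgs <- c(msgs, "row (miRNA) and column (disease) identifiers are required")
  else {
    if (anyDuplicated(rn)) msgs <- c(msgs, "miRNA identifiers must be unique")
    if (anyDuplicated(cn)) msgs <- c(msgs, "disease identifiers must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AssociationMatrix
#'
#' @param values binary numeric matrix, rownames = miRNA ids, colnames =
#'   disease ids.
#' @return an [AssociationMatrix-class] object.
#' @examples
#' A <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' mirnaIds(A)
#' @export
AssociationMatrix <- function(values) {
  new("AssociationMatrix", assoc = as.matrix(values))
}

#' SimilarityMatrix: labeled symmetric similarity in [0, 1]
#'
#' Square, symmetric real matrix of pairwise similarities with identical row
#' and column identifier lists. `kind` records which of the four similarity
#' views it holds: miRNA functional similarity ("FS"), disease semantic
#' similarity ("SS"), or GIP kernel similarity for miRNAs ("GSm") or diseases
#' ("GSd"). The constructor symmetrises by averaging (M + t(M))/2; validity
#' enforces symmetry to 1e-10, range [0, 1], and a unit diagonal for the
#' SS/GSm/GSd kinds (which are exactly 1 by construction).
#'
#' @slot values numeric matrix.
#' @slot kind one of "FS", "SS", "GSm", "GSd".
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(values = "matrix", kind = "character"))

.SIM_KINDS <- c("FS", "SS", "GSm", "GSd")

setValidity("SimilarityMatrix", function(object) {
  m <- object@values
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% .SIM_KINDS)
    msgs <- c(msgs, sprintf("kind must be one of %s", paste(.SIM_KINDS, collapse = ", ")))
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "row and column identifier lists must be identical")
  if (nrow(m) && asymmetry(m) > 1e-10)
    msgs <- c(msgs, "matrix must be symmetric within 1e-10")
  if (any(m < 0) || any(m > 1))
    msgs <- c(msgs, "all entries must lie in [0, 1]")
  if (length(object@kind) == 1L && object@kind %in% c("SS", "GSm", "GSd") &&
      nrow(m) && any(abs(diag(m) - 1) > 1e-10))
    msgs <- c(msgs, sprintf("diagonal must equal 1 for kind %s", object@kind))
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' Small floating-point asymmetries (up to 1e-10) are removed by averaging
#' with the transpose; larger asymmetries fail validation.
#'
#' @param values square numeric matrix with identical row/column names.
#' @param kind one of "FS", "SS", "GSm", "GSd".
#' @return a [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, kind) {
  m <- as.matrix(values)
  if (nrow(m) == ncol(m) && asymmetry(m) <= 1e-10) m <- (m + t(m)) / 2
  new("SimilarityMatrix", values = m, kind = kind)
}

#' DiseaseDAG: rooted acyclic ancestor graph for disease terms
#'
#' MeSH-style term forest: nodes are controlled-vocabulary terms, edges point
#' from child to parent, and each disease is annotated to one or more nodes.
#' The semantic contribution of an ancestor term decays by a fixed factor
#' (0.5) per generation away from the annotated term.
#'
#' @slot nodes character vector of term identifiers.
#' @slot parents named list: node -> character vector of parent nodes (empty
#'   for roots).
#' @slot annotation named list: disease identifier -> character vector of
#'   annotated nodes.
#' @slot decay numeric, the per-generation contribution decay (fixed at 0.5).
#' @seealso [dagContribution()], [semanticSimilarity()], [readDiseaseDAG()]
#' @exportClass DiseaseDAG
setClass("DiseaseDAG", representation(
  nodes = "character", parents = "list", annotation = "list",
  decay = "numeric"))

# DFS cycle check over the child -> parent relation
.dagHasCycle <- function(nodes, parents) {
  state <- integer(length(nodes))  # 0 unvisited, 1 on stack, 2 done
  names(state) <- nodes
  visit <- function(n) {
    if (state[[n]] == 1L) return(TRUE)
    if (state[[n]] == 2L) return(FALSE)
    state[[n]] <<- 1L
    for (p in parents[[n]] %||% character()) if (visit(p)) return(TRUE)
    state[[n]] <<- 2L
    FALSE
  }
  for (n in nodes) if (visit(n)) return(TRUE)
  FALSE
}

setValidity("DiseaseDAG", function(object) {
  msgs <- character()
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "node identifiers must be unique")
  if (!identical(object@decay, 0.5)) msgs <- c(msgs, "decay must be 0.5")
  badEdge <- setdiff(unlist(object@parents), object@nodes)
  if (length(badEdge))
    msgs <- c(msgs, sprintf("parent edges reference unknown nodes: %s",
                            paste(badEdge, collapse = ", ")))
  if (length(object@annotation)) {
    if (is.null(names(object@annotation)) || any(names(object@annotation) == ""))
      msgs <- c(msgs, "annotation list must be named by disease identifier")
    badAnn <- setdiff(unlist(object@annotation), object@nodes)
    if (length(badAnn))
      msgs <- c(msgs, sprintf("annotations reference unknown nodes: %s",
                              paste(badAnn, collapse = ", ")))
    if (any(lengths(object@annotation) == 0))
      msgs <- c(msgs, "every annotated disease must map to at least one node")
  }
  if (!length(msgs) && .dagHasCycle(object@nodes, object@parents))
    msgs <- c(msgs, "graph contains a cycle")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DiseaseDAG
#'
#' @param nodes character vector of term identifiers.
#' @param parents named list mapping each node to its parent nodes; nodes
#'   absent from the list are roots.
#' @param annotation named list mapping disease identifiers to annotated
#'   nodes.
#' @return a [DiseaseDAG-class] object.
#' @examples
#' # three-term chain: G is the grandparent of D
#' dag <- DiseaseDAG(c("G", "P", "D"),
#'   parents = list(D = "P", P = "G"),
#'   annotation = list(dD = "D", dP = "P"))
#' semanticValue(dag, "dD")  # 1 + 0.5 + 0.25
#' @export
DiseaseDAG <- function(nodes, parents = list(), annotation = list()) {
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in names(parents)) full[[n]] <- as.character(parents[[n]])
  full <- lapply(full, function(p) p %||% character())
  new("DiseaseDAG", nodes = as.character(nodes), parents = full,
      annotation = lapply(annotation, as.character), decay = 0.5)
}

#' CrossFeatureSet: the four interacted feature blocks
#'
#' Holds one feature block per cross feature D1..D4, each the concatenation of
#' one miRNA-side and one disease-side high-order feature view:
#' D1 = (FS-code, SS-code), D2 = (GSm-code, SS-code), D3 = (FS-code,
#' GSd-code), D4 = (GSm-code, GSd-code). All blocks cover the same samples.
#'
#' @slot D1,D2,D3,D4 numeric matrices with one row per sample.
#' @seealso [buildCrossFeatures()]
#' @exportClass CrossFeatureSet
setClass("CrossFeatureSet", representation(
  D1 = "matrix", D2 = "matrix", D3 = "matrix", D4 = "matrix"))

setValidity("CrossFeatureSet", function(object) {
  ns <- c(nrow(object@D1), nrow(object@D2), nrow(object@D3), nrow(object@D4))
  ws <- c(ncol(object@D1), ncol(object@D2), ncol(object@D3), ncol(object@D4))
  msgs <- character()
  if (length(unique(ns)) != 1L) msgs <- c(msgs, "all blocks must have the same sample count")
  if (length(unique(ws)) != 1L) msgs <- c(msgs, "all blocks must have the same width")
  if (length(msgs)) msgs else TRUE
})

#' EncoderStack: fitted greedy layer-wise stacked autoencoder
#'
#' Per-layer encode/decode weights of a stacked autoencoder trained greedily:
#' layer 1 reconstructs the input, each later layer reconstructs the previous
#' layer's code. Encoding composes the per-layer maps sigmoid(W1 x + b1).
#'
#' @slot layers list with one element per layer: W1, b1 (encode), W2, b2
#'   (decode), and the per-epoch training objective `lossHistory`.
#' @slot inputDim integer, width of the training input.
#' @slot config the [saeConfig()] list used for training.
#' @seealso [trainSAE()], [encode()]
#' @exportClass EncoderStack
setClass("EncoderStack", representation(
  layers = "list", inputDim = "integer", config = "list"))

setValidity("EncoderStack", function(object) {
  msgs <- character()
  din <- object@inputDim
  for (l in object@layers) {
    if (!all(c("W1", "b1", "W2", "b2") %in% names(l))) {
      msgs <- c(msgs, "each layer needs W1, b1, W2, b2"); break
    }
    if (nrow(l$W1) != din || ncol(l$W2) != din) {
      msgs <- c(msgs, "encode/decode at each layer must preserve that layer's input width")
      break
    }
    din <- ncol(l$W1)
  }
  if (length(msgs)) msgs else TRUE
})

#' PMDFIModel: fitted stacking ensemble
#'
#' Four probability random forests — one per cross-feature block — whose
#' out-of-fold scores were stacked by a logistic-regression meta-learner with
#' weights `weights` and intercept `intercept`. The final score of a sample is
#' sigmoid(intercept + sum(weights * base probabilities)).
#'
#' @slot forests list of 4 fitted `ranger` probability forests.
#' @slot weights numeric length-4 meta-learner weights.
#' @slot intercept numeric meta-learner intercept.
#' @slot stackFolds integer, internal folds used for out-of-fold stacking.
#' @slot forestConfig the [forestConfig()] list used for the base learners.
#' @slot seed integer training seed.
#' @seealso [fitPMDFI()], [predictPairs()]
#' @exportClass PMDFIModel
setClass("PMDFIModel", representation(
  forests = "list", weights = "numeric", intercept = "numeric",
  stackFolds = "integer", forestConfig = "list", seed = "integer"))

setValidity("PMDFIModel", function(object) {
  msgs <- character()
  if (length(object@forests) != 4L) msgs <- c(msgs, "exactly 4 base forests required")
  if (length(object@weights) != 4L) msgs <- c(msgs, "exactly 4 meta weights required")
  if (length(object@intercept) != 1L) msgs <- c(msgs, "intercept must be scalar")
  if (length(msgs)) msgs else TRUE
})
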