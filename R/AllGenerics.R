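#' Accessors for pmdfi containers
#'
#' `assocMatrix` returns the binary adjacency matrix; `mirnaIds` and
#' `diseaseIds` its row/column identifiers. `simMatrix` returns the numeric
#' similarity matrix, `simKind` its view label, `entityIds` its identifiers.
#' `crossBlock` extracts one of the four cross-feature blocks.
#'
#' @param x a pmdfi S4 object.
#' @param which for `crossBlock`, one of "D1", "D2", "D3", "D4".
#' @return the underlying matrix or character vector.
#' @name accessors
#' @examples
#' A <- AssociationMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("d1", "d2"))))
#' assocMatrix(A)
#' diseaseIds(A)
NULL

#' @rdname accessors
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))
#' @rdname accessors
#' @export
setGeneric("mirnaIds", function(x) standardGeneric("mirnaIds"))
#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))
#' @rdname accessors
#' @export
setGeneric("simMatrix", function(x) standardGeneric("simMatrix"))
#' @rdname accessors
#' @export
setGeneric("simKind", function(x) standardGeneric("simKind"))
#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))
#' @rdname accessors
#' @export
setGeneric("crossBlock", function(x, which) standardGeneric("crossBlock"))

#' Encode data through a fitted stacked autoencoder
#'
#' @param object an [EncoderStack-class].
#' @param X numeric matrix, one sample per row, width equal to the stack's
#'   training input width.
#' @return matrix of codes, width = final layer size, values in (0, 1).
#' @seealso [trainSAE()]
#' @export
setGeneric("encode", function(object, X) standardGeneric("encode"))

#' @rdname accessors
#' @export
setMethod("assocMatrix", "AssociationMatrix", function(x) x@assoc)
#' @rdname accessors
#' @export
setMethod("mirnaIds", "AssociationMatrix", function(x) rownames(x@assoc))
#' @rdname accessors
#' @export
setMethod("diseaseIds", "AssociationMatrix", function(x) colnames(x@assoc))
#' @rdname accessors
#' @export
setMethod("simMatrix", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("simKind", "SimilarityMatrix", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("entityIds", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("crossBlock", "CrossFeatureSet", function(x, which) {
  which <- match.arg(which, c("D1", "D2", "D3", "D4"))
  slot(x, which)
})

setMethod("show", "AssociationMatrix", function(object) {
  m <- object@assoc
  cat(sprintf("AssociationMatrix: %d miRNAs x %d diseases, %d associations (density %.3f)\n",
              nrow(m), ncol(m), sum(m), mean(m)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  m <- object@values
  off <- m[upper.tri(m)]
  cat(sprintf("SimilarityMatrix <%s>: %d x %d, off-diagonal range [%.3f, %.3f]\n",
              object@kind, nrow(m), ncol(m),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
})

setMethod("show", "DiseaseDAG", function(object) {
  nEdges <- sum(lengths(object@parents))
  cat(sprintf("DiseaseDAG: %d terms, %d child->parent edges, %d annotated diseases\n",
              length(object@nodes), nEdges, length(object@annotation)))
})

setMethod("show", "CrossFeatureSet", function(object) {
  cat(sprintf("CrossFeatureSet: %d samples, block width %d (D1..D4)\n",
              nrow(object@D1), ncol(object@D1)))
})

setMethod("show", "EncoderStack", function(object) {
  widths <- vapply(object@layers, function(l) ncol(l$W1), integer(1))
  cat(sprintf("EncoderStack: input %d -> %s\n", object@inputDim,
              paste(widths, collapse = " -> ")))
})

setMethod("show", "PMDFIModel", function(object) {
  cat(sprintf(
    "PMDFIModel: 4 forests (%d trees each) + logistic meta-learner\n  weights: %s  intercept: %.4f\n",
    object@forestConfig$nTrees,
    paste(sprintf("%.3f", object@weights), collapse = " "), object@intercept))
})
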