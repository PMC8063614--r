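#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed` and restores
#' the caller's RNG state afterwards, so library functions never perturb the
#' global random stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a top-level seed; keeps all randomness traceable to
# one integer while staying inside 32-bit range
deriveSeed <- function(seed, offset) {
  (as.integer(seed) * 97L + as.integer(offset)) %% 2147480009L
}

#' @noRd
isBinaryMatrix <- function(m) {
  is.numeric(m) && all(m %in% c(0, 1))
}

# largest absolute asymmetry of a square matrix
asymmetry <- function(m) max(abs(m - t(m)))

# stratified fold assignment: near-equal fold sizes within each class
stratifiedFolds <- function(labels, folds, seed) {
  withSeed(seed, {
    assign <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    assign
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
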