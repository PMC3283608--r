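## Internal helpers: classed conditions and seeded evaluation.

#' @importFrom methods new validObject is slot show
#' @importFrom stats predict sd setNames
#' @importFrom utils packageVersion read.table write.table
#' @importFrom e1071 svm
#' @importFrom Biostrings AAStringSet writeXStringSet width
#' @importClassesFrom Biostrings AAStringSet
NULL

## Signal a classed error so callers can dispatch on the failure mode,
## e.g. tryCatch(..., SequenceTooShort = function(e) ...).
pcStop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "PhysChemAACError"), call = call))
}

pcWarn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "PhysChemAACWarning")))
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Stratified fold ids: within each class, a seeded random permutation of
## rep(1:k, length.out = n_class). Deterministic given (labels, k, seed).
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}
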