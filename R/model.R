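## Two-level RBF-SVM classifier: level 1 separates NR from non-NR over all
## samples; level 2 assigns predicted NRs to one of the seven subfamilies.
## libsvm (via e1071) is the SVM engine; hyperparameters (C, gamma) come from
## a 2-D grid search under stratified k-fold cross-validation.

#' Model configuration
#'
#' @slot CGrid candidate penalty parameters C (positive).
#' @slot gammaGrid candidate RBF kernel widths gamma (positive).
#' @slot cvFolds folds for the grid-search cross-validation (default 5).
#' @slot seed RNG seed controlling fold assignment.
#' @slot featureScaling per-feature z-scoring fitted on the training slice
#'   (default on; RBF kernels are scale-sensitive and the covariance
#'   components span orders of magnitude).
#' @slot classWeighting inverse-frequency class weights (default off).
#' @export
setClass("ModelConfig",
  representation(CGrid = "numeric", gammaGrid = "numeric", cvFolds = "integer",
                 seed = "integer", featureScaling = "logical",
                 classWeighting = "logical"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (length(object@CGrid) < 1L || any(object@CGrid <= 0))
    msgs <- c(msgs, "CGrid must be non-empty and positive")
  if (length(object@gammaGrid) < 1L || any(object@gammaGrid <= 0))
    msgs <- c(msgs, "gammaGrid must be non-empty and positive")
  if (object@cvFolds < 2L)
    msgs <- c(msgs, "cvFolds must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ModelConfig-class
#' @param CGrid,gammaGrid numeric grids; defaults are the usual coarse
#'   log2-spaced libsvm grids, C in 2^(-5..15), gamma in 2^(-15..3).
#' @param cvFolds integer >= 2.
#' @param seed integer RNG seed.
#' @param featureScaling,classWeighting logical flags.
#' @return a `ModelConfig`.
#' @export
modelConfig <- function(CGrid = 2^seq(-5, 15, by = 2),
                        gammaGrid = 2^seq(-15, 3, by = 2),
                        cvFolds = 5L, seed = 1L,
                        featureScaling = TRUE, classWeighting = FALSE) {
  new("ModelConfig", CGrid = sort(as.numeric(CGrid)),
      gammaGrid = sort(as.numeric(gammaGrid)), cvFolds = as.integer(cvFolds),
      seed = as.integer(seed), featureScaling = isTRUE(featureScaling),
      classWeighting = isTRUE(classWeighting))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d x %d (C, gamma) grid, %d-fold CV, seed %d\n",
              length(object@CGrid), length(object@gammaGrid),
              object@cvFolds, object@seed))
})

## Per-feature z-scoring statistics fitted on a training slice; constant
## features get scale 1 so they map to 0 rather than NaN.
scalingFit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

scalingApply <- function(x, stats) {
  if (is.null(stats)) return(x)
  sweep(sweep(x, 2L, stats$center, "-"), 2L, stats$scale, "/")
}

.classWeights <- function(y, enabled) {
  if (!enabled) return(NULL)
  tab <- table(y)
  w <- as.numeric(length(y) / (length(tab) * tab))
  stats::setNames(w, names(tab))
}

## One deterministic libsvm fit on (already scaled) features.
.fitSVM <- function(x, y, C, gamma, weights = NULL) {
  e1071::svm(x = x, y = y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE, class.weights = weights)
}

#' 2-D grid search for (C, gamma)
#'
#' Evaluates every (C, gamma) pair of the configured grids by stratified
#' `cvFolds`-fold cross-validated overall accuracy and returns the maximizer.
#' Fold assignment is seeded from `cfg@seed`, so the search is deterministic.
#' Ties prefer the smaller C, then the smaller gamma (the smoother model).
#' If the smallest class has fewer members than `cvFolds`, the fold count is
#' reduced to that size (with a warning) down to 2; below 2 it is an error.
#'
#' @param features numeric sample x feature matrix.
#' @param labels factor or character vector of class labels.
#' @param cfg a [ModelConfig-class].
#' @return list with `C`, `gamma`, `cvAccuracy` (fraction), and `folds` used.
#' @export
gridSearch <- function(features, labels, cfg = modelConfig()) {
  y <- droplevels(as.factor(labels))
  minClass <- min(table(y))
  k <- cfg@cvFolds
  if (minClass < 2L)
    pcStop("TooFewSamples",
           sprintf("smallest class has %d sample(s); at least 2 are required", minClass))
  if (minClass < k) {
    k <- minClass
    pcWarn("FoldReduction",
           sprintf("reduced CV folds from %d to %d (smallest class size)", cfg@cvFolds, k))
  }
  folds <- stratifiedFolds(y, k, cfg@seed)
  weights <- .classWeights(y, cfg@classWeighting)
  ## Pre-split scaled features once per fold; scaling is fitted on the
  ## training folds only.
  foldData <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    st <- if (cfg@featureScaling) scalingFit(features[tr, , drop = FALSE]) else NULL
    list(xtr = scalingApply(features[tr, , drop = FALSE], st),
         ytr = y[tr],
         xte = scalingApply(features[!tr, , drop = FALSE], st),
         yte = y[!tr])
  })
  n <- length(y)
  best <- list(C = NA_real_, gamma = NA_real_, cvAccuracy = -1)
  for (C in cfg@CGrid) for (g in cfg@gammaGrid) {
    correct <- 0L
    for (fd in foldData) {
      fit <- .fitSVM(fd$xtr, fd$ytr, C, g, weights)
      correct <- correct + sum(predict(fit, fd$xte) == fd$yte)
    }
    acc <- correct / n
    if (acc > best$cvAccuracy + 1e-12) best <- list(C = C, gamma = g, cvAccuracy = acc)
  }
  best$folds <- k
  best
}

#' Trained two-level classifier
#'
#' @slot level1 fitted binary libsvm model (NR vs nonNR).
#' @slot level2 fitted 7-class libsvm model (one-vs-one voting), trained on
#'   NR samples only.
#' @slot level1Params,level2Params named numeric `c(C, gamma, cvAccuracy)`.
#' @slot scaling1,scaling2 per-level feature scaling statistics (or NULL).
#' @slot encoderConfig the [EncoderConfig-class] used for the features.
#' @slot propertyVersion version tag of the property table used.
#' @slot config the [ModelConfig-class] used for training.
#' @slot fingerprint short text fingerprint of the training set.
#' @export
setClass("TwoLevelModel",
  representation(level1 = "ANY", level2 = "ANY",
                 level1Params = "numeric", level2Params = "numeric",
                 scaling1 = "ANY", scaling2 = "ANY",
                 encoderConfig = "EncoderConfig",
                 propertyVersion = "character",
                 config = "ModelConfig",
                 fingerprint = "character"))

setMethod("show", "TwoLevelModel", function(object) {
  cat("TwoLevelModel (RBF SVM, one-vs-one voting at level 2)\n")
  cat(sprintf("  level 1 (NR vs nonNR):  C = %g, gamma = %g, CV acc = %.2f%%\n",
              object@level1Params["C"], object@level1Params["gamma"],
              100 * object@level1Params["cvAccuracy"]))
  cat(sprintf("  level 2 (subfamilies):  C = %g, gamma = %g, CV acc = %.2f%%\n",
              object@level2Params["C"], object@level2Params["gamma"],
              100 * object@level2Params["cvAccuracy"]))
  cat(sprintf("  encoder: maxLag = %d; property table %s; training set %s\n",
              object@encoderConfig@maxLag, object@propertyVersion,
              object@fingerprint))
})

.datasetFingerprint <- function(dataset) {
  sprintf("n=%d;res=%d", length(dataset),
          sum(Biostrings::width(sequences(dataset))))
}

#' Train the two-level classifier
#'
#' Encodes the dataset, runs [gridSearch()] independently for the level-1
#' binary task (all samples) and the level-2 subfamily task (NR samples
#' only), then fits the two final RBF SVMs on their full training slices
#' with the selected (C, gamma). Feature scaling statistics are fitted per
#' level on the respective training slice.
#'
#' @param dataset an [NRDataset-class] containing both NR and nonNR samples,
#'   with NR samples covering at least two subfamilies; alternatively a
#'   precomputed feature matrix may be supplied via `features`.
#' @param cfg a [ModelConfig-class].
#' @param encoderCfg an [EncoderConfig-class].
#' @param table a [PropertyTable-class].
#' @param features optional precomputed feature matrix (rows aligned with
#'   `dataset`); encoding is skipped when given.
#' @return a [TwoLevelModel-class].
#' @export
trainTwoLevel <- function(dataset, cfg = modelConfig(),
                          encoderCfg = encoderConfig(),
                          table = referencePropertyTable(),
                          features = NULL) {
  y1 <- factor(level1Labels(dataset), levels = c("NR", "nonNR"))
  y2all <- subfamilyLabels(dataset)
  nrIdx <- which(y2all != "nonNR")
  if (length(nrIdx) == 0L || length(nrIdx) == length(dataset))
    pcStop("TooFewSamples", "training set must contain both NR and nonNR samples")
  if (length(unique(y2all[nrIdx])) < 2L)
    pcStop("TooFewSamples", "NR samples must cover at least two subfamilies")
  if (is.null(features)) features <- encodeSequences(dataset, encoderCfg, table)

  gs1 <- gridSearch(features, y1, cfg)
  y2 <- factor(y2all[nrIdx], levels = SUBFAMILY_LEVELS)
  y2 <- droplevels(y2)
  gs2 <- gridSearch(features[nrIdx, , drop = FALSE], y2, cfg)

  st1 <- if (cfg@featureScaling) scalingFit(features) else NULL
  fit1 <- .fitSVM(scalingApply(features, st1), y1, gs1$C, gs1$gamma,
                  .classWeights(y1, cfg@classWeighting))
  st2 <- if (cfg@featureScaling) scalingFit(features[nrIdx, , drop = FALSE]) else NULL
  fit2 <- .fitSVM(scalingApply(features[nrIdx, , drop = FALSE], st2), y2,
                  gs2$C, gs2$gamma, .classWeights(y2, cfg@classWeighting))

  new("TwoLevelModel", level1 = fit1, level2 = fit2,
      level1Params = c(C = gs1$C, gamma = gs1$gamma, cvAccuracy = gs1$cvAccuracy),
      level2Params = c(C = gs2$C, gamma = gs2$gamma, cvAccuracy = gs2$cvAccuracy),
      scaling1 = st1, scaling2 = st2,
      encoderConfig = encoderCfg, propertyVersion = tableVersion(table),
      config = cfg, fingerprint = .datasetFingerprint(dataset))
}

#' Maximum query batch size accepted by predict()
#' @export
BATCH_CAP <- 500L

#' Predict NR status and subfamily for query sequences
#'
#' Each query is encoded and passed through the two-level flow: the level-1
#' SVM decides NR vs nonNR; queries predicted NR are assigned a subfamily by
#' the level-2 SVM (one-vs-one voting). Queries predicted nonNR get no
#' subfamily. Per-sequence encoder failures (too short, too many ambiguous
#' residues) are reported in the `error` column without aborting the batch.
#' At most 500 sequences are accepted per call.
#'
#' @param object a [TwoLevelModel-class].
#' @param seqs `AAStringSet`, named character vector, or [NRDataset-class].
#' @param table a [PropertyTable-class] (must match the training table
#'   version).
#' @param ... unused.
#' @return data.frame with columns `id`, `level1` ("NR"/"nonNR"),
#'   `subfamily` (`NA` for nonNR or failed records), `error` (`NA` or the
#'   failure message).
#' @export
setMethod("predict", "TwoLevelModel",
  function(object, seqs, table = referencePropertyTable(), ...) {
    if (is(seqs, "NRDataset")) seqs <- sequences(seqs)
    s <- as.character(seqs)
    if (is.null(names(s)) && !is.null(names(seqs))) names(s) <- names(seqs)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    if (length(s) > BATCH_CAP)
      pcStop("BatchTooLarge",
             sprintf("batch of %d sequences exceeds the cap of %d per call",
                     length(s), BATCH_CAP))
    if (!identical(tableVersion(table), object@propertyVersion))
      pcStop("EncoderMismatch",
             sprintf("property table '%s' does not match the model's '%s'",
                     tableVersion(table), object@propertyVersion))
    cfg <- object@encoderConfig
    P <- length(object@scaling1$center)
    if (is.null(P)) P <- length(propertyIds(table))^2 * cfg@maxLag
    out <- data.frame(id = names(s), level1 = NA_character_,
                      subfamily = NA_character_, error = NA_character_,
                      stringsAsFactors = FALSE)
    feats <- matrix(NA_real_, nrow = length(s),
                    ncol = length(propertyIds(table))^2 * cfg@maxLag)
    ok <- logical(length(s))
    for (i in seq_along(s)) {
      v <- tryCatch(suppressWarnings(encodeSequence(s[[i]], cfg, table)),
                    PhysChemAACError = function(e) e)
      if (inherits(v, "condition")) {
        out$error[i] <- conditionMessage(v)
      } else {
        feats[i, ] <- v
        ok[i] <- TRUE
      }
    }
    if (any(ok)) {
      x <- feats[ok, , drop = FALSE]
      p1 <- as.character(predict(object@level1, scalingApply(x, object@scaling1)))
      out$level1[ok] <- p1
      isNR <- ok
      isNR[ok] <- p1 == "NR"
      if (any(isNR)) {
        x2 <- feats[isNR, , drop = FALSE]
        p2 <- as.character(predict(object@level2, scalingApply(x2, object@scaling2)))
        out$subfamily[isNR] <- p2
      }
    }
    out
  })

#' Save / load a trained model archive
#'
#' The archive stores the fitted SVMs together with the encoder
#' configuration, property-table version and package version. `loadModel`
#' refuses archives whose encoder configuration or property-table version
#' does not match the running reference, so stale models cannot silently be
#' applied to differently-encoded features.
#'
#' @param model a [TwoLevelModel-class].
#' @param path file path for the archive.
#' @return `loadModel` returns the [TwoLevelModel-class]; `saveModel`
#'   returns `path` invisibly.
#' @export
saveModel <- function(model, path) {
  archive <- list(model = model,
                  packageVersion = as.character(utils::packageVersion("PhysChemAAC")),
                  propertyVersion = model@propertyVersion,
                  maxLag = model@encoderConfig@maxLag)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname saveModel
#' @param table reference [PropertyTable-class] the archive must match.
#' @export
loadModel <- function(path, table = referencePropertyTable()) {
  archive <- readRDS(path)
  if (!is.list(archive) || !is(archive$model, "TwoLevelModel"))
    pcStop("EncoderMismatch", "file is not a model archive")
  if (!identical(archive$propertyVersion, tableVersion(table)))
    pcStop("EncoderMismatch",
           sprintf("archive property table '%s' does not match the running '%s'",
                   archive$propertyVersion, tableVersion(table)))
  archive$model
}
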