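## Performance metrics (overall/per-class ACC and MCC), jackknife and k-fold
## evaluation protocols, and leave-one-property-out impact ranking.

#' Overall accuracy
#'
#' Exact ratio of correctly predicted samples to all evaluated samples.
#'
#' @param nCorrect,nTotal non-negative integers.
#' @return fraction in `[0, 1]`.
#' @export
accuracyScore <- function(nCorrect, nTotal) {
  if (nTotal < 1L) pcStop("EmptyEvaluation", "no samples were evaluated")
  nCorrect / nTotal
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. If any marginal
#' factor is zero the coefficient is taken as 0 (the conventional limit for a
#' degenerate confusion table).
#'
#' @param TP,TN,FP,FN non-negative confusion counts.
#' @return value in `[-1, 1]`.
#' @export
mccScore <- function(TP, TN, FP, FN) {
  ## products of counts overflow 32-bit ints quickly; compute in double
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom == 0) return(0)
  (TP * TN - FP * FN) / sqrt(denom)
}

## Multi-class generalization of the MCC (Gorodkin's R_K statistic) computed
## from a square confusion matrix; reduces to the binary MCC for 2 classes.
multiClassMcc <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm); c0 <- sum(diag(cm))
  t_k <- rowSums(cm)   # true counts
  p_k <- colSums(cm)   # predicted counts
  num <- c0 * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' Evaluation report
#'
#' Aggregated result of a jackknife, k-fold or holdout run: per-class
#' one-vs-rest confusion counts with ACC and MCC, overall accuracy (exact
#' correct/total) and overall MCC, plus the per-sample predictions the
#' metrics were derived from.
#'
#' @slot perClass data.frame: `class`, `TP`, `TN`, `FP`, `FN`, `ACC`, `MCC`.
#' @slot overallAcc overall accuracy (full prediction path) in `[0, 1]`.
#' @slot overallMcc overall MCC (binary MCC for 2 classes, the multi-class
#'   generalization otherwise).
#' @slot level1Acc,level2Acc accuracies of the two levels taken separately
#'   (`NA` where the protocol did not exercise a level). `level2Acc` is
#'   computed over true-NR samples only.
#' @slot protocol e.g. `"jackknife"`, `"kfold(5)"`.
#' @slot nEvaluated number of samples evaluated.
#' @slot predictions data.frame: `id`, `truth`, `predicted`, `correct`.
#' @export
setClass("EvalReport",
  representation(perClass = "data.frame", overallAcc = "numeric",
                 overallMcc = "numeric", level1Acc = "numeric",
                 level2Acc = "numeric", protocol = "character",
                 nEvaluated = "integer", predictions = "data.frame"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  ## Eq.-level self-consistency: overall accuracy must equal the mean of the
  ## per-sample correctness indicators it was derived from.
  if (nrow(object@predictions) > 0L &&
      abs(object@overallAcc - mean(object@predictions$correct)) > 1e-12)
    msgs <- c(msgs, "overallAcc does not match the stored predictions")
  if (nrow(object@perClass) > 0L && any(abs(object@perClass$MCC) > 1 + 1e-12))
    msgs <- c(msgs, "per-class MCC out of [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn EvalReport-class overall accuracy.
#' @param x,object an `EvalReport`.
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname EvalReport-class
#' @export
setMethod("overallAccuracy", "EvalReport", function(x) x@overallAcc)

#' @describeIn EvalReport-class overall MCC.
#' @export
setGeneric("overallMcc", function(x) standardGeneric("overallMcc"))

#' @rdname EvalReport-class
#' @export
setMethod("overallMcc", "EvalReport", function(x) x@overallMcc)

#' @describeIn EvalReport-class per-class metric table.
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname EvalReport-class
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@perClass)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s], %d samples\n", object@protocol, object@nEvaluated))
  pc <- object@perClass
  if (nrow(pc)) {
    cat(sprintf("  %-8s %8s %6s\n", "class", "ACC", "MCC"))
    for (r in seq_len(nrow(pc)))
      cat(sprintf("  %-8s %7.2f%% %6.2f\n", pc$class[r], 100 * pc$ACC[r], pc$MCC[r]))
  }
  cat(sprintf("  %-8s %7.2f%% %6.2f\n", "overall", 100 * object@overallAcc,
              object@overallMcc))
  if (!is.na(object@level1Acc))
    cat(sprintf("  level-1 ACC %.2f%%", 100 * object@level1Acc))
  if (!is.na(object@level2Acc))
    cat(sprintf("  level-2 ACC %.2f%% (true-NR samples)", 100 * object@level2Acc))
  if (!is.na(object@level1Acc) || !is.na(object@level2Acc)) cat("\n")
})

## One-vs-rest confusion counts + ACC/MCC rows for each class in `classes`,
## evaluated over (truth, predicted) restricted by `mask`.
.perClassRows <- function(truth, predicted, classes, mask = TRUE) {
  truth <- truth[mask]; predicted <- predicted[mask]
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl, na.rm = TRUE)
    fn <- sum(truth == cl & (is.na(predicted) | predicted != cl))
    fp <- sum(truth != cl & !is.na(predicted) & predicted == cl)
    tn <- sum(truth != cl & (is.na(predicted) | predicted != cl))
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               ACC = (tp + tn) / max(1L, tp + tn + fp + fn),
               MCC = mccScore(tp, tn, fp, fn), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Assemble an EvalReport from per-sample two-level truth and predictions.
## truth1/pred1: NR vs nonNR over all samples (may be NA if level 1 was not
## run); truth2/pred2: subfamily over true-NR samples (NA elsewhere).
.buildReport <- function(ids, truth1, pred1, truth2, pred2, protocol) {
  n <- length(ids)
  haveL1 <- !all(is.na(pred1))
  haveL2 <- !all(is.na(truth2))
  if (haveL1) {
    fullTruth <- ifelse(is.na(truth2), truth1, truth2)
    fullPred <- ifelse(!is.na(pred1) & pred1 == "nonNR", "nonNR", pred2)
    if (!haveL2) { fullTruth <- truth1; fullPred <- pred1 }
  } else {
    fullTruth <- truth2; fullPred <- pred2
  }
  correct <- !is.na(fullPred) & fullPred == fullTruth
  perClass <- NULL
  if (haveL1)
    perClass <- .perClassRows(truth1, pred1, intersect(c("NR", "nonNR"), unique(truth1)))
  if (haveL2) {
    nrMask <- !is.na(truth2)
    cls <- intersect(SUBFAMILY_LEVELS, unique(truth2[nrMask]))
    perClass <- rbind(perClass, .perClassRows(truth2, pred2, cls, nrMask))
  }
  cm <- table(factor(fullTruth, levels = unique(fullTruth)),
              factor(ifelse(is.na(fullPred), "<none>", fullPred),
                     levels = c(unique(fullTruth), "<none>")))
  cm <- cm[, seq_along(unique(fullTruth)), drop = FALSE]  # square part
  level1Acc <- if (haveL1) mean(!is.na(pred1) & pred1 == truth1) else NA_real_
  level2Acc <- if (haveL2) {
    nrMask <- !is.na(truth2)
    mean(!is.na(pred2[nrMask]) & pred2[nrMask] == truth2[nrMask])
  } else NA_real_
  new("EvalReport",
      perClass = perClass,
      overallAcc = accuracyScore(sum(correct), n),
      overallMcc = multiClassMcc(cm),
      level1Acc = level1Acc, level2Acc = level2Acc,
      protocol = protocol, nEvaluated = as.integer(n),
      predictions = data.frame(id = ids, truth = fullTruth,
                               predicted = fullPred, correct = correct,
                               stringsAsFactors = FALSE))
}

## Core cross-validation engine shared by jackknife and k-fold. For each
## fold, retrains the requested level(s) with fixed (C, gamma) on the
## training slice and predicts the held-out slice through the two-level flow.
.cvEvaluate <- function(features, dataset, cfg, fixedParams, level, foldIds,
                        protocol, evalFolds = NULL) {
  n <- length(dataset)
  y1 <- level1Labels(dataset)
  y2 <- subfamilyLabels(dataset)
  truth2 <- ifelse(y2 == "nonNR", NA_character_, y2)
  runL1 <- level %in% c("1", "both")
  runL2 <- level %in% c("2", "both")
  if (level == "2" && any(y2 == "nonNR"))
    pcStop("TooFewSamples", "level-2 evaluation requires an NR-only dataset")
  pred1 <- rep(NA_character_, n)
  pred2 <- rep(NA_character_, n)
  weights1 <- .classWeights(factor(y1), cfg@classWeighting)
  if (is.null(evalFolds)) evalFolds <- sort(unique(foldIds))
  for (f in evalFolds) {
    te <- which(foldIds == f)
    tr <- which(foldIds != f)
    if (runL1) {
      st <- if (cfg@featureScaling) scalingFit(features[tr, , drop = FALSE]) else NULL
      fit <- .fitSVM(scalingApply(features[tr, , drop = FALSE], st),
                     factor(y1[tr], levels = c("NR", "nonNR")),
                     fixedParams$level1[["C"]], fixedParams$level1[["gamma"]],
                     weights1)
      pred1[te] <- as.character(predict(fit, scalingApply(features[te, , drop = FALSE], st)))
    }
    if (runL2) {
      trNR <- tr[y2[tr] != "nonNR"]
      yTrain <- factor(y2[trNR], levels = SUBFAMILY_LEVELS)
      present <- droplevels(yTrain)
      if (nlevels(present) < nlevels(droplevels(factor(truth2[!is.na(truth2)],
                                                       levels = SUBFAMILY_LEVELS))))
        pcWarn("ClassDropped",
               "a training slice lost an entire subfamily; proceeding with the rest")
      st <- if (cfg@featureScaling) scalingFit(features[trNR, , drop = FALSE]) else NULL
      fit <- .fitSVM(scalingApply(features[trNR, , drop = FALSE], st), present,
                     fixedParams$level2[["C"]], fixedParams$level2[["gamma"]],
                     .classWeights(present, cfg@classWeighting))
      ## at level "both" only samples predicted NR reach level 2
      teNR <- if (level == "both") te[pred1[te] == "NR"] else te
      if (length(teNR))
        pred2[teNR] <- as.character(predict(fit, scalingApply(
          features[teNR, , drop = FALSE], st)))
    }
  }
  if (!runL1) { y1use <- rep(NA_character_, n); p1use <- rep(NA_character_, n) }
  else { y1use <- y1; p1use <- pred1 }
  .buildReport(names(sequences(dataset)), y1use, p1use,
               if (runL2) truth2 else rep(NA_character_, n),
               if (runL2) pred2 else rep(NA_character_, n),
               protocol)
}

## Grid-search (C, gamma) once on the full dataset for the requested levels.
.searchFixedParams <- function(features, dataset, cfg, level) {
  out <- list()
  if (level %in% c("1", "both")) {
    gs <- gridSearch(features, factor(level1Labels(dataset)), cfg)
    out$level1 <- c(C = gs$C, gamma = gs$gamma)
  }
  if (level %in% c("2", "both")) {
    y2 <- subfamilyLabels(dataset)
    idx <- which(y2 != "nonNR")
    gs <- gridSearch(features[idx, , drop = FALSE],
                     droplevels(factor(y2[idx], levels = SUBFAMILY_LEVELS)), cfg)
    out$level2 <- c(C = gs$C, gamma = gs$gamma)
  }
  out
}

#' Jackknife (leave-one-out) evaluation
#'
#' The protocol of record: hyperparameters (C, gamma) are first fixed — by a
#' single grid search on the full dataset unless supplied — and then each
#' sample in turn is predicted by a model retrained on all remaining samples.
#' Once the hyperparameters are fixed no randomness remains, so two runs on
#' the same dataset yield identical reports. Refitting the search inside
#' every fold (leakage-free but much slower) is available via
#' `strictSearch = TRUE`; the report's protocol string records it.
#'
#' @param dataset an [NRDataset-class]; for `level = "2"` it must be NR-only.
#' @param cfg a [ModelConfig-class].
#' @param fixedParams optional list with `level1` and/or `level2`, each a
#'   named vector `c(C =, gamma =)`; when `NULL` a grid search on the full
#'   dataset supplies them.
#' @param level `"1"` (NR vs nonNR, all samples), `"2"` (subfamilies,
#'   NR-only dataset), or `"both"` (full two-level flow).
#' @param encoderCfg,table encoder settings (see [encodeSequence()]).
#' @param features optional precomputed feature matrix.
#' @param strictSearch re-run the grid search inside every fold.
#' @return an [EvalReport-class].
#' @export
jackknifeEval <- function(dataset, cfg = modelConfig(), fixedParams = NULL,
                          level = c("both", "1", "2"),
                          encoderCfg = encoderConfig(),
                          table = referencePropertyTable(),
                          features = NULL, strictSearch = FALSE) {
  level <- match.arg(level)
  n <- length(dataset)
  if (n < 3L) pcStop("TooFewSamples", "jackknife needs at least 3 samples")
  if (is.null(features)) features <- encodeSequences(dataset, encoderCfg, table)
  if (strictSearch) {
    ## leakage-free variant: refresh the (C, gamma) search inside every fold
    ## on the n-1 training samples, then combine the held-out predictions
    folds <- lapply(seq_len(n), function(i) {
      fp <- suppressWarnings(
        .searchFixedParams(features[-i, , drop = FALSE], dataset[-i], cfg, level))
      r <- .cvEvaluate(features, dataset, cfg, fp, level,
                       replace(rep(2L, n), i, 1L), "jackknife", evalFolds = 1L)
      r@predictions[i, , drop = FALSE]
    })
    preds <- do.call(rbind, folds)
    ## rebuild the report from the strict per-sample predictions
    truth1 <- if (level %in% c("1", "both")) level1Labels(dataset) else rep(NA_character_, n)
    pred1 <- if (level %in% c("1", "both"))
      ifelse(preds$predicted == "nonNR", "nonNR", "NR") else rep(NA_character_, n)
    y2 <- subfamilyLabels(dataset)
    truth2 <- if (level %in% c("2", "both"))
      ifelse(y2 == "nonNR", NA_character_, y2) else rep(NA_character_, n)
    pred2 <- if (level %in% c("2", "both"))
      ifelse(preds$predicted %in% SUBFAMILY_LEVELS, preds$predicted, NA_character_)
    else rep(NA_character_, n)
    return(.buildReport(names(sequences(dataset)), truth1, pred1, truth2, pred2,
                        "jackknife(strict-search)"))
  }
  if (is.null(fixedParams))
    fixedParams <- .searchFixedParams(features, dataset, cfg, level)
  .cvEvaluate(features, dataset, cfg, fixedParams, level, seq_len(n), "jackknife")
}

#' Stratified k-fold evaluation
#'
#' Same aggregation as [jackknifeEval()] but over seeded stratified folds.
#' With `k` equal to the dataset size the partition coincides with the
#' jackknife.
#'
#' @inheritParams jackknifeEval
#' @param k number of folds (>= 2).
#' @return an [EvalReport-class].
#' @export
kfoldEval <- function(dataset, cfg = modelConfig(), k = 5L, fixedParams = NULL,
                      level = c("both", "1", "2"),
                      encoderCfg = encoderConfig(),
                      table = referencePropertyTable(), features = NULL) {
  level <- match.arg(level)
  n <- length(dataset)
  if (k < 2L || n < k) pcStop("TooFewSamples", "need 2 <= k <= n folds")
  if (is.null(features)) features <- encodeSequences(dataset, encoderCfg, table)
  if (is.null(fixedParams))
    fixedParams <- .searchFixedParams(features, dataset, cfg, level)
  strat <- if (level == "2") subfamilyLabels(dataset) else level1Labels(dataset)
  foldIds <- if (k == n) seq_len(n) else stratifiedFolds(strat, k, cfg@seed)
  .cvEvaluate(features, dataset, cfg, fixedParams, level, foldIds,
              sprintf("kfold(%d)", k))
}

#' Leave-one-property-out impact ranking
#'
#' Quantifies how much each of the ten physicochemical scales contributes to
#' classification: for every property, the dataset is re-encoded with the
#' nine remaining scales, the grid search is refreshed, and a jackknife run
#' measures the accuracy drop relative to the full ten-property baseline.
#' The property whose removal drops the overall success rate the most ranks
#' first; equal drops share a rank.
#'
#' @inheritParams jackknifeEval
#' @param level `"1"` ranks impact on the NR/nonNR task over all samples;
#'   `"2"` on the subfamily task over the NR samples only.
#' @return data.frame sorted by descending drop: `property`, `ablatedAcc`,
#'   `accuracyDrop`, `rank` (ties share the smallest rank), plus attribute
#'   `baselineAcc`.
#' @export
rankPropertyImpact <- function(dataset, cfg = modelConfig(),
                               level = c("1", "2"),
                               encoderCfg = encoderConfig(),
                               table = referencePropertyTable()) {
  level <- match.arg(level)
  if (level == "2") {
    keep <- subfamilyLabels(dataset) != "nonNR"
    dataset <- dataset[keep]
  }
  evalAcc <- function(tbl) {
    feats <- encodeSequences(dataset, encoderCfg, tbl)
    rep <- jackknifeEval(dataset, cfg, level = level, encoderCfg = encoderCfg,
                         table = tbl, features = feats)
    overallAccuracy(rep)
  }
  baseline <- evalAcc(table)
  ids <- propertyIds(table)
  drops <- vapply(seq_along(ids), function(p) {
    baseline - evalAcc(table[-p])
  }, numeric(1L))
  ablated <- baseline - drops
  out <- data.frame(property = ids, ablatedAcc = ablated, accuracyDrop = drops,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$accuracyDrop, out$property), ]
  out$rank <- rank(-out$accuracyDrop, ties.method = "min")
  rownames(out) <- NULL
  attr(out, "baselineAcc") <- baseline
  out
}
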