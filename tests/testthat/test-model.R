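test_that("grid search is deterministic, honors single-point grids and breaks ties smoothly", {
  ds <- tinyDataset(seed = 5)
  feats <- encodeSequences(ds)
  y <- factor(level1Labels(ds))
  ## single-point grid: no search, score reported
  gs1 <- gridSearch(feats, y, tinyConfig(C = 8, gamma = 2^-9))
  expect_equal(gs1$C, 8)
  expect_equal(gs1$gamma, 2^-9)
  expect_gte(gs1$cvAccuracy, 0)
  ## determinism: same inputs and seed, identical outcome
  cfg <- modelConfig(CGrid = 2^c(0, 2, 4), gammaGrid = 2^c(-11, -9, -7),
                     cvFolds = 3L, seed = 9L)
  gsA <- gridSearch(feats, y, cfg)
  gsB <- gridSearch(feats, y, cfg)
  expect_identical(gsA, gsB)
  ## tie-break: on perfectly separable data many pairs reach the same score;
  ## the reported pair must be the (smallest C, smallest gamma) among them
  scores <- vapply(cfg@CGrid, function(C) vapply(cfg@gammaGrid, function(g) {
    gridSearch(feats, y, modelConfig(CGrid = C, gammaGrid = g, cvFolds = 3L,
                                     seed = 9L))$cvAccuracy
  }, numeric(1)), numeric(3))  # gamma x C
  topGamma <- cfg@gammaGrid[row(scores)[scores == max(scores)]]
  topC <- cfg@CGrid[col(scores)[scores == max(scores)]]
  expect_equal(gsA$cvAccuracy, max(scores))
  expect_equal(gsA$C, min(topC))
  expect_equal(gsA$gamma, min(topGamma[topC == min(topC)]))
})

test_that("grid search reduces folds for small classes and rejects singletons", {
  ds <- tinyDataset(seed = 6, sizes = c(12L, 2L, 12L))
  feats <- encodeSequences(ds)
  expect_warning(
    gs <- gridSearch(feats, factor(subfamilyLabels(ds)), tinyConfig()),
    class = "FoldReduction")
  expect_identical(gs$folds, 2L)
  y <- factor(c("A", rep("B", 35)))
  expect_error(gridSearch(feats, y, tinyConfig()), class = "TooFewSamples")
})

test_that("two-level training fits level 2 on NR samples only, with grid-member parameters", {
  ds <- tinyDataset(seed = 5)
  cfg <- modelConfig(CGrid = 2^c(0, 2), gammaGrid = 2^c(-11, -9), cvFolds = 3L, seed = 1L)
  model <- suppressWarnings(trainTwoLevel(ds, cfg))
  expect_s4_class(model, "TwoLevelModel")
  expect_true(model@level1Params["C"] %in% cfg@CGrid)
  expect_true(model@level2Params["gamma"] %in% cfg@gammaGrid)
  ## level separation: replacing the nonNR block leaves level 2 untouched
  labs <- subfamilyLabels(ds)
  nrOnly <- ds[labs != "nonNR"]
  other <- sequences(sampleDataset(generatorSpec(nClasses = 2, classSizes = c(8L, 8L),
                                                 separation = 0, seed = 77,
                                                 lengthRange = c(60L, 120L))))
  names(other) <- paste0("alt_", seq_along(other))
  swapped <- NRDataset(c(sequences(nrOnly), other),
                       c(subfamilyLabels(nrOnly), rep("nonNR", 16L)))
  model2 <- suppressWarnings(trainTwoLevel(swapped, cfg))
  expect_identical(model@level2Params, model2@level2Params)
  expect_equal(model@level2$SV, model2@level2$SV)
  expect_equal(model@level2$coefs, model2@level2$coefs)
  ## degenerate inputs
  allNR <- NRDataset(sequences(nrOnly), subfamilyLabels(nrOnly))
  expect_error(trainTwoLevel(allNR, cfg), class = "TooFewSamples")
  oneSub <- NRDataset(sequences(ds), ifelse(labs == "nonNR", "nonNR", "NR1"))
  expect_error(trainTwoLevel(oneSub, cfg), class = "TooFewSamples")
})

test_that("retraining with the same seed reproduces hyperparameters and predictions", {
  ds <- tinyDataset(seed = 8)
  cfg <- modelConfig(CGrid = 2^c(0, 4), gammaGrid = 2^c(-11, -8), cvFolds = 3L, seed = 3L)
  mA <- suppressWarnings(trainTwoLevel(ds, cfg))
  mB <- suppressWarnings(trainTwoLevel(ds, cfg))
  expect_identical(mA@level1Params, mB@level1Params)
  expect_identical(mA@level2Params, mB@level2Params)
  probe <- sampleDataset(generatorSpec(nClasses = 2, classSizes = c(5L, 5L),
                                       separation = 5, seed = 99,
                                       lengthRange = c(60L, 120L)))
  expect_identical(predict(mA, sequences(probe)), predict(mB, sequences(probe)))
})

test_that("prediction follows the two-level flow and reports per-record failures", {
  ds <- tinyDataset(seed = 5)
  model <- suppressWarnings(trainTwoLevel(ds, tinyConfig()))
  probe <- sequences(ds)[c(1L, 30L)]  # one NR-like, one nonNR-like
  res <- predict(model, probe)
  expect_identical(names(res), c("id", "level1", "subfamily", "error"))
  expect_true(all(res$level1 %in% c("NR", "nonNR")))
  expect_true(all(is.na(res$subfamily[res$level1 == "nonNR"])))
  expect_true(all(res$subfamily[res$level1 == "NR"] %in% SUBFAMILY_LEVELS))
  ## encoder failure on one record does not abort the batch
  mixed <- c(good = as.character(probe[[1]]), bad = "ACDE")
  resM <- predict(model, mixed)
  expect_true(is.na(resM$level1[2]))
  expect_match(resM$error[2], "length")
  expect_false(is.na(resM$level1[1]))
})

test_that("prediction enforces the 500-sequence batch cap", {
  ds <- tinyDataset(seed = 5)
  model <- suppressWarnings(trainTwoLevel(ds, tinyConfig()))
  set.seed(1)
  batch <- vapply(1:501, function(i)
    paste(sample(AA_ALPHABET20, 30, replace = TRUE), collapse = ""), character(1))
  names(batch) <- paste0("q", 1:501)
  expect_error(predict(model, batch), class = "BatchTooLarge")
  res <- predict(model, batch[1:500])
  expect_identical(nrow(res), 500L)
  expect_true(all(!is.na(res$level1)))
})

test_that("model archives round-trip and refuse mismatched encoders", {
  ds <- tinyDataset(seed = 5)
  model <- suppressWarnings(trainTwoLevel(ds, tinyConfig()))
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  probe <- sequences(ds)[1:4]
  expect_identical(predict(back, probe), predict(model, probe))
  ## stale archive: property-table version mismatch is refused
  archive <- readRDS(path)
  archive$propertyVersion <- "reference-0.9"
  saveRDS(archive, path)
  expect_error(loadModel(path), class = "EncoderMismatch")
  saveRDS(list(not = "a model"), path)
  expect_error(loadModel(path), class = "EncoderMismatch")
})
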