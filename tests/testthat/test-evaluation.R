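test_that("accuracy is the exact ratio of correct to evaluated samples", {
  expect_equal(accuracyScore(10, 10), 1)
  expect_equal(accuracyScore(13, 16), 0.8125)
  expect_equal(accuracyScore(0, 5), 0)
  expect_error(accuracyScore(0, 0), class = "EmptyEvaluation")
})

test_that("MCC matches direct formula evaluation over enumerated confusion tables", {
  expect_equal(mccScore(50, 50, 0, 0), 1)
  expect_equal(mccScore(25, 25, 25, 25), 0)
  expect_equal(mccScore(45, 480, 20, 5), naiveMcc(45, 480, 20, 5), tolerance = 1e-12)
  ## enumerated tables, including degenerate marginals (convention: 0)
  counts <- expand.grid(TP = c(0, 1, 7), TN = c(0, 3, 12),
                        FP = c(0, 2, 5), FN = c(0, 1, 9))
  for (r in seq_len(nrow(counts))) {
    with(counts[r, ], {
      expect_equal(mccScore(TP, TN, FP, FN), naiveMcc(TP, TN, FP, FN),
                   tolerance = 1e-12)
      expect_lte(abs(mccScore(TP, TN, FP, FN)), 1)
      ## binary class swap (TP<->TN, FP<->FN) leaves MCC unchanged
      expect_equal(mccScore(TP, TN, FP, FN), mccScore(TN, TP, FN, FP))
    })
  }
  ## large counts must not overflow integer arithmetic
  expect_equal(mccScore(5e4L, 5e4L, 1L, 1L), naiveMcc(5e4, 5e4, 1, 1), tolerance = 1e-12)
})

test_that("jackknife runs one round per sample and is self-consistent and unique", {
  ds <- tinyDataset(seed = 21, sizes = c(10L, 10L, 10L))
  feats <- encodeSequences(ds)
  fixed <- list(level1 = c(C = 4, gamma = 2^-9), level2 = c(C = 4, gamma = 2^-9))
  rep1 <- jackknifeEval(ds, tinyConfig(), fixedParams = fixed, features = feats)
  expect_s4_class(rep1, "EvalReport")
  expect_identical(rep1@nEvaluated, 30L)
  expect_identical(nrow(rep1@predictions), 30L)  # one round per sample
  ## overall accuracy equals the mean of per-sample correctness (exactly)
  expect_identical(overallAccuracy(rep1), mean(rep1@predictions$correct))
  ## per-class rows recompute from the stored predictions
  pc <- perClassMetrics(rep1)
  expect_true(all(c("NR", "nonNR") %in% pc$class))
  expect_true(all(abs(pc$MCC) <= 1))
  nrRow <- pc[pc$class == "NR", ]
  expect_identical(nrRow$TP + nrRow$TN + nrRow$FP + nrRow$FN, 30L)
  ## no randomness remains once hyperparameters are fixed
  rep2 <- jackknifeEval(ds, tinyConfig(), fixedParams = fixed, features = feats)
  expect_identical(rep1@predictions, rep2@predictions)
  expect_error(jackknifeEval(ds[1:2], tinyConfig()), class = "TooFewSamples")
})

test_that("k-fold evaluation is seeded, stratified, and reduces to the jackknife at k = n", {
  ds <- tinyDataset(seed = 22, sizes = c(9L, 9L, 9L))
  feats <- encodeSequences(ds)
  fixed <- list(level1 = c(C = 4, gamma = 2^-9), level2 = c(C = 4, gamma = 2^-9))
  k1 <- kfoldEval(ds, tinyConfig(), k = 3L, fixedParams = fixed, features = feats)
  k2 <- kfoldEval(ds, tinyConfig(), k = 3L, fixedParams = fixed, features = feats)
  expect_identical(k1@predictions, k2@predictions)
  expect_match(k1@protocol, "kfold")
  ## leave-one-out equivalence
  kn <- kfoldEval(ds, tinyConfig(), k = length(ds), fixedParams = fixed, features = feats)
  jk <- jackknifeEval(ds, tinyConfig(), fixedParams = fixed, features = feats)
  expect_identical(kn@predictions$predicted, jk@predictions$predicted)
  expect_error(kfoldEval(ds, tinyConfig(), k = 1L), class = "TooFewSamples")
})

test_that("level-2 evaluation sees NR samples only and reports subfamily metrics", {
  ds3 <- sampleDataset(generatorSpec(nClasses = 3, classSizes = c(10L, 10L, 10L),
                                     separation = 5, seed = 31,
                                     lengthRange = c(60L, 120L)))
  fixed <- list(level2 = c(C = 4, gamma = 2^-9))
  rep2 <- jackknifeEval(ds3, tinyConfig(), fixedParams = fixed, level = "2")
  expect_identical(sort(perClassMetrics(rep2)$class), sort(c("NR1", "NR2", "NR3")))
  expect_identical(rep2@level2Acc, overallAccuracy(rep2))
  ## mixed dataset is rejected for a level-2-only protocol
  mixed <- tinyDataset(seed = 5)
  expect_error(jackknifeEval(mixed, tinyConfig(), fixedParams = fixed, level = "2"),
               class = "TooFewSamples")
})

test_that("property impact ranking returns a permutation of the ten scales", {
  ds <- tinyDataset(seed = 23, sizes = c(8L, 8L, 8L))
  rk <- rankPropertyImpact(ds, tinyConfig(), level = "1")
  expect_identical(nrow(rk), 10L)
  expect_setequal(rk$property, paste0("PC", 1:10))
  expect_true(all(diff(rk$accuracyDrop) <= 0))  # sorted by drop, descending
  expect_true(all(rk$rank >= 1 & rk$rank <= 10))
  ## equal drops share a rank
  if (anyDuplicated(rk$accuracyDrop)) {
    dup <- rk$accuracyDrop == rk$accuracyDrop[duplicated(rk$accuracyDrop)][1]
    expect_identical(length(unique(rk$rank[dup])), 1L)
  }
  expect_equal(attr(rk, "baselineAcc") - rk$accuracyDrop, rk$ablatedAcc,
               tolerance = 1e-12)
})
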