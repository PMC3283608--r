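test_that("sanitization normalizes case and strips whitespace, digits and ambiguity codes", {
  expect_identical(as.character(sanitizeSequence("acdEFG")), "ACDEFG")
  expect_identical(as.character(sanitizeSequence("AC DE\n FG")), "ACDEFG")
  expect_identical(as.character(sanitizeSequence("ACDE12FG\r\n")), "ACDEFG")
  ## non-canonical residues dropped with a counted warning
  expect_warning(s <- sanitizeSequence("ACXDEFGHIKLMN"), class = "DroppedResidues")
  expect_identical(as.character(s), "ACDEFGHIKLMN")
  expect_identical(attr(s, "dropped"), 1L)
  ## strict mode refuses them; >10% ambiguous always refused
  expect_error(sanitizeSequence("ACXDE", strict = TRUE), class = "TooManyAmbiguous")
  expect_error(sanitizeSequence("AXXXC"), class = "TooManyAmbiguous")
  expect_error(sanitizeSequence("   "), class = "EmptySequence")
  expect_error(sanitizeSequence("AC-DE"), class = "EmptySequence")
})

test_that("the physicochemical matrix is a per-residue lookup with exact row means", {
  pt <- referencePropertyTable()
  m <- physChemMatrix("AAAA")
  v <- propertyValues(m)
  expect_identical(dim(v), c(10L, 4L))
  expect_true(all(v == v[, 1]))  # homopolymer: identical columns
  expect_equal(propertyMeans(m), standardizedValues(pt)[, "A"], ignore_attr = TRUE)
  s <- randomSequence(30, seed = 9)
  m2 <- physChemMatrix(s)
  expect_identical(dim(propertyValues(m2)), c(10L, 30L))
  ## row means equal an independent per-row loop
  direct <- apply(propertyValues(m2), 1, function(r) sum(r) / length(r))
  expect_equal(propertyMeans(m2), direct, tolerance = 1e-12, ignore_attr = TRUE)
  ## entries are table lookups
  chars <- strsplit(s, "")[[1]]
  expect_equal(propertyValues(m2)[3, 17], standardizedValues(pt)["PC3", chars[17]],
               ignore_attr = TRUE)
})

test_that("auto- and cross-covariance match a brute-force double-loop oracle", {
  s <- randomSequence(25, seed = 4)
  m <- physChemMatrix(s)
  ref <- naiveEncode(s, maxLag = 10L)
  fmap <- featureIndexMap()
  for (r in seq_len(nrow(fmap))) {
    got <- if (fmap$kind[r] == "AC")
      autoCovariance(m, fmap$property1[r], fmap$lag[r])
    else
      crossCovariance(m, fmap$property1[r], fmap$property2[r], fmap$lag[r])
    expect_lt(abs(got - ref[r]), 1e-12)
  }
  ## cross-covariance is direction-dependent
  expect_false(isTRUE(all.equal(crossCovariance(m, 1, 4, 3),
                                crossCovariance(m, 4, 1, 3))))
  ## homopolymer: all deviations vanish
  mh <- physChemMatrix(strrep("L", 15))
  expect_equal(autoCovariance(mh, 2, 5), 0)
  expect_equal(crossCovariance(mh, 2, 7, 5), 0)
  ## L = g + 1 leaves a single product term
  m2 <- physChemMatrix("AC")
  z <- propertyValues(m2); mu <- propertyMeans(m2)
  expect_equal(autoCovariance(m2, 1, 1),
               unname((z[1, 1] - mu[1]) * (z[1, 2] - mu[1])))
  expect_error(autoCovariance(m2, 1, 2), class = "LagTooLarge")
  expect_error(crossCovariance(m, 3, 3, 1), class = "SameProperty")
})

test_that("encoding yields the canonical 1000-component vector and obeys the dimension law", {
  v <- encodeSequence(randomSequence(40, seed = 11))
  expect_length(v, 1000L)
  fmap <- featureIndexMap()
  expect_identical(names(v), fmap$component)
  expect_identical(sum(fmap$kind == "AC"), 100L)
  expect_identical(sum(fmap$kind == "CC"), 900L)
  expect_false(anyDuplicated(fmap$component) > 0)
  ## dimension law: 100 * LG components for the 10-property table
  for (LG in c(1L, 2L, 3L, 5L, 10L)) {
    cfg <- encoderConfig(maxLag = LG)
    expect_length(encodeSequence(randomSequence(30, seed = LG), cfg), 100L * LG)
  }
  ## homopolymer encodes to the zero vector
  expect_true(all(encodeSequence(strrep("A", 20)) == 0))
  ## pure function: bit-identical across calls
  s <- randomSequence(60, seed = 2)
  expect_identical(encodeSequence(s), encodeSequence(s))
  ## minimum length L >= LG + 1
  expect_error(encodeSequence(strrep("AC", 5)), class = "SequenceTooShort")
  expect_silent(v11 <- encodeSequence(randomSequence(11, seed = 1)))
  expect_length(v11, 1000L)
})

test_that("encoding assembles exactly the covariance operations, across many random sequences", {
  set.seed(77)
  lens <- sample(11:60, 12, replace = TRUE)
  for (k in seq_along(lens)) {
    s <- randomSequence(lens[k], seed = 1000 + k)
    expect_lt(max(abs(encodeSequence(s) - naiveEncode(s))), 1e-12)
  }
})

test_that("a sequence set encodes to a row-per-sequence feature matrix", {
  seqs <- c(a = randomSequence(20, 1), b = randomSequence(35, 2))
  feats <- encodeSequences(seqs)
  expect_identical(dim(feats), c(2L, 1000L))
  expect_identical(rownames(feats), c("a", "b"))
  expect_equal(feats["b", ], encodeSequence(seqs[["b"]]))
  ## reduced property tables shrink the dimension to P^2 * LG
  sub <- referencePropertyTable()[-4]
  expect_identical(ncol(encodeSequences(seqs, table = sub)), 810L)
})
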