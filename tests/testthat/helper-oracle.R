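## Independent brute-force reference implementations used as oracles.
## These deliberately share no code with the package internals: plain
## double loops over positions, scales looked up cell by cell.

## residues drawn uniformly; deterministic given seed
randomSequence <- function(L, seed) {
  set.seed(seed)
  paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
}

## naive standardization of one 20-value scale (population SD)
naiveStandardize <- function(x) {
  mu <- sum(x) / 20
  sigma <- sqrt(sum((x - mu)^2) / 20)
  (x - mu) / sigma
}

## naive full encoder: z-matrix cell by cell, covariances by double loop,
## canonical order (AC by property then lag; CC by i1, i2 != i1, lag)
naiveEncode <- function(seq, maxLag = 10L, table = referencePropertyTable()) {
  chars <- strsplit(seq, "")[[1]]
  raw <- rawValues(table)
  P <- nrow(raw)
  L <- length(chars)
  z <- matrix(0, P, L)
  for (i in seq_len(P)) {
    zi <- naiveStandardize(raw[i, ])
    for (j in seq_len(L)) z[i, j] <- zi[chars[j]]
  }
  mu <- numeric(P)
  for (i in seq_len(P)) mu[i] <- sum(z[i, ]) / L
  covIJ <- function(i1, i2, g) {
    tot <- 0
    for (j in seq_len(L - g)) tot <- tot + (z[i1, j] - mu[i1]) * (z[i2, j + g] - mu[i2])
    tot / (L - g)
  }
  out <- numeric(0)
  for (i in seq_len(P)) for (g in seq_len(maxLag)) out <- c(out, covIJ(i, i, g))
  for (i1 in seq_len(P)) for (i2 in seq_len(P)) {
    if (i1 == i2) next
    for (g in seq_len(maxLag)) out <- c(out, covIJ(i1, i2, g))
  }
  out
}

## direct MCC formula evaluation (independent arithmetic path)
naiveMcc <- function(tp, tn, fp, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

## small labeled dataset for fast model tests: two well-separated classes
## plus a third subfamily, tiny sizes, short sequences
tinyDataset <- function(seed = 5, sizes = c(12L, 12L, 12L)) {
  ds3 <- sampleDataset(generatorSpec(nClasses = 3, classSizes = sizes,
                                     separation = 5, seed = seed,
                                     lengthRange = c(60L, 120L)))
  ## relabel the third class as nonNR so the set exercises both levels
  labs <- subfamilyLabels(ds3)
  labs[labs == "NR3"] <- "nonNR"
  NRDataset(sequences(ds3), labs)
}

## one-point grids keep model tests fast and deterministic
tinyConfig <- function(seed = 1, C = 4, gamma = 2^-9) {
  modelConfig(CGrid = C, gammaGrid = gamma, cvFolds = 3L, seed = seed)
}
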