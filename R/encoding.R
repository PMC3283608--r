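## Sequence sanitization, the physicochemical property matrix, and the
## auto-/cross-covariance (ACC) transform into a fixed-length feature vector.

NON_CANONICAL <- c("B", "J", "O", "U", "X", "Z", "*")

#' Encoder configuration
#'
#' @slot maxLag maximum positional lag of the covariance transform
#'   (default 10). With P properties the feature dimension is
#'   `P^2 * maxLag` (1000 for the reference ten properties).
#' @slot strict if `TRUE`, non-canonical residues are an error instead of
#'   being dropped with a warning.
#' @export
setClass("EncoderConfig",
  representation(maxLag = "integer", strict = "logical"))

setValidity("EncoderConfig", function(object) {
  if (length(object@maxLag) != 1L || is.na(object@maxLag) || object@maxLag < 1L)
    return("maxLag must be a single integer >= 1")
  TRUE
})

#' @rdname EncoderConfig-class
#' @param maxLag integer >= 1, maximum lag (default 10).
#' @param strict logical, reject non-canonical residues instead of dropping.
#' @return an `EncoderConfig` object.
#' @export
encoderConfig <- function(maxLag = 10L, strict = FALSE) {
  new("EncoderConfig", maxLag = as.integer(maxLag), strict = isTRUE(strict))
}

setMethod("show", "EncoderConfig", function(object) {
  cat(sprintf("EncoderConfig: maxLag = %d, strict = %s\n",
              object@maxLag, object@strict))
})

#' Sanitize a raw protein sequence
#'
#' Uppercases the input, strips whitespace and digits, and removes
#' non-canonical residue codes (B, J, O, U, X, Z, `*`), emitting a warning
#' with the number of residues dropped. In strict mode a non-canonical
#' residue is an error. More than 10% non-canonical residues is always an
#' error (the input is considered untrustworthy).
#'
#' @param raw character scalar, the raw residue string.
#' @param strict logical; if `TRUE` any non-canonical residue is an error.
#' @return character scalar of canonical residues, with attribute `dropped`
#'   giving the number of residues removed.
#' @examples
#' sanitizeSequence("ac dE\nFG")  # "ACDEFG"
#' @export
sanitizeSequence <- function(raw, strict = FALSE) {
  if (length(raw) != 1L || is.na(raw))
    pcStop("EmptySequence", "sequence must be a single non-missing string")
  s <- toupper(gsub("[[:space:][:digit:]]", "", raw))
  if (nchar(s) == 0L)
    pcStop("EmptySequence", "sequence is empty after whitespace removal")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% AA_ALPHABET20)
  invalid <- bad & !(chars %in% NON_CANONICAL)
  if (any(invalid))
    pcStop("EmptySequence",
           sprintf("sequence contains characters that are not residue codes: %s",
                   paste(unique(chars[invalid]), collapse = "")))
  nBad <- sum(bad)
  if (nBad > 0L) {
    if (isTRUE(strict))
      pcStop("TooManyAmbiguous",
             sprintf("strict mode: %d non-canonical residue(s) present", nBad))
    if (nBad / length(chars) > 0.10)
      pcStop("TooManyAmbiguous",
             sprintf("%d of %d residues (%.1f%%) are non-canonical; input rejected",
                     nBad, length(chars), 100 * nBad / length(chars)))
    pcWarn("DroppedResidues",
           sprintf("dropped %d non-canonical residue(s)", nBad))
  }
  out <- paste(chars[!bad], collapse = "")
  if (nchar(out) == 0L)
    pcStop("EmptySequence", "no canonical residues remain after sanitization")
  attr(out, "dropped") <- nBad
  out
}

#' Physicochemical property matrix of a sequence
#'
#' The P x L matrix whose row i holds the standardized value of property i at
#' each residue position, together with the per-property row means over the
#' sequence (the centering terms of the covariance transform).
#'
#' @slot values numeric P x L matrix (rows = properties, columns = positions).
#' @slot means numeric vector of P row means.
#' @export
setClass("PhysChemMatrix",
  representation(values = "matrix", means = "numeric"))

setValidity("PhysChemMatrix", function(object) {
  if (nrow(object@values) != length(object@means))
    return("means must have one entry per property row")
  TRUE
})

#' @rdname PhysChemMatrix-class
#' @param seq sanitized residue string (character or `AAString`).
#' @param table a [PropertyTable-class]; defaults to the reference table.
#' @return a `PhysChemMatrix`.
#' @examples
#' m <- physChemMatrix("ACDEFGHIKLMNPQRSTVWY")
#' dim(propertyValues(m))  # 10 x 20
#' @export
physChemMatrix <- function(seq, table = referencePropertyTable()) {
  s <- as.character(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% AA_ALPHABET20))
    pcStop("EmptySequence", "sequence must be sanitized before building the matrix")
  z <- standardizedValues(table)
  vals <- z[, chars, drop = FALSE]
  colnames(vals) <- NULL
  new("PhysChemMatrix", values = vals, means = rowMeans(vals))
}

#' @describeIn PhysChemMatrix-class the P x L value matrix.
#' @param x,object a `PhysChemMatrix`.
#' @export
setGeneric("propertyValues", function(x) standardGeneric("propertyValues"))

#' @rdname PhysChemMatrix-class
#' @export
setMethod("propertyValues", "PhysChemMatrix", function(x) x@values)

#' @describeIn PhysChemMatrix-class per-property means over the sequence.
#' @export
setGeneric("propertyMeans", function(x) standardGeneric("propertyMeans"))

#' @rdname PhysChemMatrix-class
#' @export
setMethod("propertyMeans", "PhysChemMatrix", function(x) x@means)

setMethod("show", "PhysChemMatrix", function(object) {
  cat(sprintf("PhysChemMatrix: %d properties x %d positions\n",
              nrow(object@values), ncol(object@values)))
})

.checkLag <- function(m, g) {
  L <- ncol(m@values)
  if (g < 1L || g >= L)
    pcStop("LagTooLarge",
           sprintf("lag %d is out of range for a sequence of length %d (need 1 <= lag <= L-1)", g, L))
}

#' Auto-covariance of one property at a given lag
#'
#' Mean product of mean-centered values of the same property at positions
#' separated by `lag`:
#' `sum_{j=1..L-g} (v[i,j] - mu_i)(v[i,j+g] - mu_i) / (L - g)`,
#' where `mu_i` is the full-sequence row mean.
#'
#' @param m a [PhysChemMatrix-class].
#' @param property row index or property id.
#' @param lag integer lag, `1 <= lag <= L - 1`.
#' @return numeric scalar.
#' @export
autoCovariance <- function(m, property, lag) {
  .checkLag(m, lag)
  if (is.character(property)) property <- match(property, rownames(m@values))
  v <- m@values[property, ] - m@means[property]
  L <- length(v)
  sum(v[seq_len(L - lag)] * v[seq_len(L - lag) + lag]) / (L - lag)
}

#' Cross-covariance of two different properties at a given lag
#'
#' Mean product of the mean-centered values of property `property1` at
#' position j and property `property2` at position j + lag. Not symmetric in
#' the property pair.
#'
#' @inheritParams autoCovariance
#' @param property1,property2 distinct row indices or property ids.
#' @return numeric scalar.
#' @export
crossCovariance <- function(m, property1, property2, lag) {
  .checkLag(m, lag)
  if (is.character(property1)) property1 <- match(property1, rownames(m@values))
  if (is.character(property2)) property2 <- match(property2, rownames(m@values))
  if (property1 == property2)
    pcStop("SameProperty", "property1 and property2 must differ; use autoCovariance()")
  v1 <- m@values[property1, ] - m@means[property1]
  v2 <- m@values[property2, ] - m@means[property2]
  L <- length(v1)
  sum(v1[seq_len(L - lag)] * v2[seq_len(L - lag) + lag]) / (L - lag)
}

#' Canonical index map of the feature vector
#'
#' Component order is fixed: first all auto-covariance components ordered by
#' (property ascending, lag ascending), then all cross-covariance components
#' ordered by (property1 ascending, property2 ascending skipping the
#' diagonal, lag ascending). With P properties and maximum lag LG the vector
#' has `P*LG + P*(P-1)*LG = P^2*LG` components (1000 with the defaults).
#'
#' @param table a [PropertyTable-class].
#' @param config an [EncoderConfig-class].
#' @return data.frame with columns `component` (tag), `kind` ("AC"/"CC"),
#'   `property1`, `property2` (`NA` for AC), `lag`.
#' @export
featureIndexMap <- function(table = referencePropertyTable(),
                            config = encoderConfig()) {
  ids <- propertyIds(table)
  P <- length(ids); LG <- config@maxLag
  ac <- data.frame(
    kind = "AC",
    property1 = rep(ids, each = LG),
    property2 = NA_character_,
    lag = rep(seq_len(LG), times = P),
    stringsAsFactors = FALSE)
  pairs <- expand.grid(i2 = seq_len(P), i1 = seq_len(P))  # i2 varies fastest
  pairs <- pairs[pairs$i1 != pairs$i2, c("i1", "i2")]
  cc <- data.frame(
    kind = "CC",
    property1 = rep(ids[pairs$i1], each = LG),
    property2 = rep(ids[pairs$i2], each = LG),
    lag = rep(seq_len(LG), times = nrow(pairs)),
    stringsAsFactors = FALSE)
  out <- rbind(ac, cc)
  out$component <- ifelse(out$kind == "AC",
    sprintf("AC_%s_lag%d", out$property1, out$lag),
    sprintf("CC_%s_%s_lag%d", out$property1, out$property2, out$lag))
  rownames(out) <- NULL
  out[, c("component", "kind", "property1", "property2", "lag")]
}

#' Encode one protein sequence as an ACC feature vector
#'
#' Builds the physicochemical matrix of the (sanitized) sequence and applies
#' the auto-/cross-covariance transform at lags `1..maxLag`, in the canonical
#' component order of [featureIndexMap()]. Sequences of length `<= maxLag`
#' are rejected: every lag up to `maxLag` must leave at least one product
#' term.
#'
#' @param seq residue string (character or `AAString`); sanitized first.
#' @param config an [EncoderConfig-class].
#' @param table a [PropertyTable-class].
#' @return named numeric vector of `P^2 * maxLag` components.
#' @examples
#' v <- encodeSequence(paste(rep("ACDEFGHIKL", 3), collapse = ""))
#' length(v)  # 1000
#' @export
encodeSequence <- function(seq, config = encoderConfig(),
                           table = referencePropertyTable()) {
  s <- sanitizeSequence(as.character(seq), strict = config@strict)
  LG <- config@maxLag
  L <- nchar(s)
  if (L <= LG)
    pcStop("SequenceTooShort",
           sprintf("sequence length %d must exceed the maximum lag %d", L, LG))
  m <- physChemMatrix(s, table)
  P <- nrow(m@values)
  Mc <- m@values - m@means   # recycles the means column-wise by row
  ## cov[i1, i2, g] = sum_j Mc[i1, j] * Mc[i2, j + g] / (L - g)
  cov <- array(0, dim = c(P, P, LG))
  for (g in seq_len(LG)) {
    cov[, , g] <- (Mc[, seq_len(L - g), drop = FALSE] %*%
                   t(Mc[, seq_len(L - g) + g, drop = FALSE])) / (L - g)
  }
  ac <- numeric(P * LG)
  for (i in seq_len(P)) ac[(i - 1L) * LG + seq_len(LG)] <- cov[i, i, ]
  ccList <- vector("list", P * (P - 1L))
  k <- 0L
  for (i1 in seq_len(P)) for (i2 in seq_len(P)) {
    if (i1 == i2) next
    k <- k + 1L
    ccList[[k]] <- cov[i1, i2, ]
  }
  out <- c(ac, unlist(ccList))
  names(out) <- featureIndexMap(table, config)$component
  out
}

#' Encode a set of sequences into a feature matrix
#'
#' @param seqs an `AAStringSet`, named character vector, or
#'   [NRDataset-class]; names become row names.
#' @inheritParams encodeSequence
#' @return numeric matrix, one row per sequence, columns in canonical
#'   component order.
#' @export
encodeSequences <- function(seqs, config = encoderConfig(),
                            table = referencePropertyTable()) {
  if (is(seqs, "NRDataset")) seqs <- sequences(seqs)
  s <- as.character(seqs)
  if (is.null(names(s)) && !is.null(names(seqs))) names(s) <- names(seqs)
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  feats <- t(vapply(s, encodeSequence,
                    numeric(length(propertyIds(table))^2 * config@maxLag),
                    config = config, table = table))
  rownames(feats) <- names(s)
  feats
}
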