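## Ten amino-acid physicochemical property scales and their standardization.

#' One-letter codes of the 20 native amino acids, alphabetical
#'
#' Canonical residue ordering used throughout the package: every property
#' table column, residue-frequency profile and serialized output follows
#' this order.
#'
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Identifiers of the ten reference property scales (PC1..PC10)
#' @export
PC_IDS <- paste0("PC", 1:10)
PC_NAMES <- c(
  PC1  = "hydrophobicity",
  PC2  = "hydrophilicity",
  PC3  = "side-chain mass",
  PC4  = "pK1 (alpha-COOH)",
  PC5  = "pK2 (NH3)",
  PC6  = "PI (25C)",
  PC7  = "average buried volume",
  PC8  = "molecular weight",
  PC9  = "side-chain volume",
  PC10 = "mean polarity"
)

## Reference scale values, one row per residue (A..Y), columns PC1..PC10.
## Embedded constants; the table version below is bumped if they ever change.
.PC_RAW <- matrix(c(
  ##  PC1    PC2    PC3   PC4    PC5    PC6    PC7     PC8    PC9   PC10
    0.62, -0.50,  15, 2.35,  9.87,  6.11,  91.50,  89.09,  27.5, -0.06,  # A
    0.29, -1.00,  47, 1.71, 10.78,  5.02, 117.70, 121.20,  44.6,  1.36,  # C
   -0.90,  3.00,  59, 1.88,  9.60,  2.98, 124.50, 133.10,  40.0, -0.80,  # D
   -0.74,  3.00,  73, 2.19,  9.67,  3.08, 155.10, 147.10,  62.0, -0.77,  # E
    1.19, -2.50,  91, 2.58,  9.24,  5.91, 203.40, 165.20, 115.5,  1.27,  # F
    0.48,  0.00,   1, 2.34,  9.60,  6.06,  66.40,  75.07,   0.0, -0.41,  # G
   -0.40, -0.50,  82, 1.78,  8.97,  7.64, 167.30, 155.20,  79.0,  0.49,  # H
    1.38, -1.80,  57, 2.32,  9.76,  6.04, 168.80, 131.20,  93.5,  1.31,  # I
   -1.50,  3.00,  73, 2.20,  8.90,  9.47, 171.30, 146.20, 100.0, -1.18,  # K
    1.06, -1.80,  57, 2.36,  9.60,  6.04, 167.90, 131.20,  93.5,  1.21,  # L
    0.64, -1.30,  75, 2.28,  9.21,  5.74, 170.80, 149.20,  94.1,  1.27,  # M
   -0.78,  0.20,  58, 2.18,  9.09, 10.76, 135.20, 132.10,  58.7, -0.48,  # N
    0.12,  0.00,  42, 1.99, 10.60,  6.30, 129.30, 115.10,  41.9,  0.00,  # P
   -0.85,  0.20,  72, 2.17,  9.13,  5.65, 161.10, 146.20,  80.7, -0.73,  # Q
   -2.53,  3.00, 101, 2.18,  9.09, 10.76, 202.00, 174.20, 105.0, -0.84,  # R
   -0.18,  0.30,  31, 2.21,  9.15,  5.68,  99.10, 105.10,  29.3, -0.50,  # S
   -0.05, -0.40,  45, 2.15,  9.12,  5.60, 122.10, 119.10,  51.3, -0.27,  # T
    1.08, -1.50,  43, 2.29,  9.74,  6.02, 141.70, 117.20,  71.5,  1.09,  # V
    0.81, -3.40, 130, 2.38,  9.39,  5.88, 237.60, 204.20, 145.5,  0.88,  # W
    0.26, -2.30, 107, 2.20,  9.11,  5.63, 203.60, 181.20, 117.3,  0.33   # Y
), nrow = 20, ncol = 10, byrow = TRUE,
   dimnames = list(AA_ALPHABET20, PC_IDS))

.PC_TABLE_VERSION <- "reference-1.0"

#' Physicochemical property table
#'
#' Holds a set of amino-acid property scales, both as supplied (`raw`) and
#' after zero-mean/unit-variance standardization over the 20 native residues
#' (`standardized`). Rows are properties, columns the 20 residues in
#' alphabetical one-letter order.
#'
#' @slot propertyIds character vector of property identifiers (rows).
#' @slot raw numeric matrix, properties x 20 residues, original scale values.
#' @slot standardized numeric matrix of the same shape after [standardizeScale()]
#'   has been applied to each row.
#' @slot version character tag identifying the table contents.
#'
#' @seealso [referencePropertyTable()], [standardizeScale()]
#' @export
setClass("PropertyTable",
  representation(
    propertyIds  = "character",
    raw          = "matrix",
    standardized = "matrix",
    version      = "character"
  )
)

setValidity("PropertyTable", function(object) {
  msgs <- character()
  p <- length(object@propertyIds)
  if (p < 1L) msgs <- c(msgs, "at least one property is required")
  for (nm in c("raw", "standardized")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || nrow(m) != p || ncol(m) != 20L)
      msgs <- c(msgs, sprintf("'%s' must be a numeric %d x 20 matrix", nm, p))
    else if (!identical(colnames(m), AA_ALPHABET20))
      msgs <- c(msgs, sprintf("'%s' columns must be the 20 residues A..Y", nm))
  }
  if (length(msgs) == 0L) {
    z <- object@standardized
    if (max(abs(rowMeans(z))) > 1e-8)
      msgs <- c(msgs, "standardized rows must have mean 0")
    sds <- sqrt(rowMeans((z - rowMeans(z))^2))
    if (max(abs(sds - 1)) > 1e-8)
      msgs <- c(msgs, "standardized rows must have population SD 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Standardize a 20-residue property scale
#'
#' Zero-centers and unit-scales a property scale over the 20 native amino
#' acids: `(x - mean(x)) / sd_pop(x)`, where the standard deviation is the
#' population form (divisor 20) because the 20-residue alphabet is the
#' complete population, not a sample. The conversion is idempotent: applying
#' it to already-standardized values returns them unchanged.
#'
#' @param x numeric vector of 20 scale values, one per residue.
#' @return numeric vector of 20 standardized values, same order as the input.
#' @examples
#' z <- standardizeScale(rawValues(referencePropertyTable())["PC1", ])
#' mean(z)  # 0 to machine precision
#' @export
standardizeScale <- function(x) {
  if (length(x) != 20L)
    pcStop("BadScaleLength", sprintf("a property scale must have 20 values, got %d", length(x)))
  if (anyNA(x))
    pcStop("BadScaleLength", "property scale contains missing values")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    pcStop("ZeroVarianceScale",
           "all 20 values of the property scale are identical; standardization is undefined")
  (x - mu) / sigma
}

#' Construct a property table
#'
#' Builds a [PropertyTable-class] from raw scale values; standardized values
#' are computed row-wise with [standardizeScale()].
#'
#' @param raw numeric matrix, properties x 20 residues; columns must be
#'   named with (or be in) the alphabetical one-letter order `AA_ALPHABET20`.
#' @param version character tag stored with the table.
#' @return a `PropertyTable` object.
#' @export
propertyTable <- function(raw, version = "user") {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20L)
    pcStop("BadScaleLength", "raw table must have 20 columns (one per residue)")
  if (is.null(colnames(raw))) colnames(raw) <- AA_ALPHABET20
  raw <- raw[, AA_ALPHABET20, drop = FALSE]
  if (is.null(rownames(raw))) rownames(raw) <- paste0("PC", seq_len(nrow(raw)))
  z <- t(apply(raw, 1L, standardizeScale))
  dimnames(z) <- dimnames(raw)
  new("PropertyTable", propertyIds = rownames(raw), raw = raw,
      standardized = z, version = version)
}

#' Reference table of the ten physicochemical scales
#'
#' Returns the immutable built-in table of ten property scales
#' (hydrophobicity, hydrophilicity, side-chain mass, pK1, pK2, PI, average
#' buried volume, molecular weight, side-chain volume, mean polarity) for the
#' 20 native amino acids, with standardized values precomputed.
#'
#' @return a [PropertyTable-class] with 10 properties, version-stamped.
#' @examples
#' pt <- referencePropertyTable()
#' rawValues(pt)["PC1", "A"]
#' @export
referencePropertyTable <- function() {
  propertyTable(t(.PC_RAW), version = .PC_TABLE_VERSION)
}

#' @describeIn PropertyTable-class property identifiers (row order).
#' @param x,object a `PropertyTable`.
#' @export
setGeneric("propertyIds", function(x) standardGeneric("propertyIds"))

#' @rdname PropertyTable-class
#' @export
setMethod("propertyIds", "PropertyTable", function(x) x@propertyIds)

#' @describeIn PropertyTable-class raw scale values (properties x residues).
#' @export
setGeneric("rawValues", function(x) standardGeneric("rawValues"))

#' @rdname PropertyTable-class
#' @export
setMethod("rawValues", "PropertyTable", function(x) x@raw)

#' @describeIn PropertyTable-class standardized values (properties x residues).
#' @export
setGeneric("standardizedValues", function(x) standardGeneric("standardizedValues"))

#' @rdname PropertyTable-class
#' @export
setMethod("standardizedValues", "PropertyTable", function(x) x@standardized)

#' @describeIn PropertyTable-class version tag of the table.
#' @export
setGeneric("tableVersion", function(x) standardGeneric("tableVersion"))

#' @rdname PropertyTable-class
#' @export
setMethod("tableVersion", "PropertyTable", function(x) x@version)

#' @rdname PropertyTable-class
#' @param i index or property ids to keep (subsets properties, not residues).
#' @export
setMethod("[", "PropertyTable", function(x, i) {
  raw <- x@raw[i, , drop = FALSE]
  new("PropertyTable", propertyIds = rownames(raw), raw = raw,
      standardized = x@standardized[i, , drop = FALSE],
      version = paste0(x@version, "-subset"))
})

setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable (version %s): %d properties x 20 residues\n",
              object@version, length(object@propertyIds)))
  cat("properties:", paste(object@propertyIds, collapse = ", "), "\n")
})

#' Write / read a property table as tab-separated text
#'
#' Serialization is residue-major: a header row of property ids, then one row
#' per amino acid (alphabetical order) with its raw scale values. Cell values
#' round-trip exactly at 15 significant digits.
#'
#' @param x a [PropertyTable-class].
#' @param path file path.
#' @return `readPropertyTable` returns a `PropertyTable` rebuilt from the file
#'   (standardized values are recomputed); `writePropertyTable` returns `path`
#'   invisibly.
#' @export
writePropertyTable <- function(x, path) {
  df <- as.data.frame(t(rawValues(x)))
  df <- cbind(aa = rownames(df), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePropertyTable
#' @param version character tag for the rebuilt table.
#' @export
readPropertyTable <- function(path, version = "imported") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  aa <- df[[1L]]
  if (!setequal(aa, AA_ALPHABET20))
    pcStop("BadScaleLength", "property table file must have one row per residue A..Y")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- aa
  propertyTable(t(m[AA_ALPHABET20, , drop = FALSE]), version = version)
}
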