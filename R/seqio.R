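## FASTA and label-manifest I/O, and the labeled dataset container.

#' Closed label vocabulary
#'
#' `nonNR` plus the seven nuclear-receptor subfamilies in canonical order:
#' NR1 (thyroid hormone like), NR2 (HNF4-like), NR3 (estrogen like),
#' NR4 (nerve growth factor IB-like), NR5 (fushi tarazu-F1 like),
#' NR6 (germ cell nuclear factor like), NR0 (knirps like).
#'
#' @export
SUBFAMILY_LEVELS <- c("NR1", "NR2", "NR3", "NR4", "NR5", "NR6", "NR0")

#' @rdname SUBFAMILY_LEVELS
#' @export
LABEL_VOCAB <- c("nonNR", SUBFAMILY_LEVELS)

#' Labeled protein dataset
#'
#' Couples an `AAStringSet` of (raw) sequences with a label per sequence from
#' the closed vocabulary `LABEL_VOCAB`. Order follows the source FASTA file
#' for reproducibility.
#'
#' @slot sequences `AAStringSet`; names are sequence ids.
#' @slot labels character vector, one label per sequence.
#' @export
setClass("NRDataset",
  representation(sequences = "AAStringSet", labels = "character"))

setValidity("NRDataset", function(object) {
  msgs <- character()
  if (length(object@sequences) != length(object@labels))
    msgs <- c(msgs, "one label per sequence is required")
  if (!all(object@labels %in% LABEL_VOCAB))
    msgs <- c(msgs, sprintf("labels must be in {%s}", paste(LABEL_VOCAB, collapse = ", ")))
  if (anyDuplicated(names(object@sequences)))
    msgs <- c(msgs, "sequence ids must be unique")
  if (length(msgs)) msgs else TRUE
})

#' @rdname NRDataset-class
#' @param sequences `AAStringSet` or named character vector.
#' @param labels character labels from `LABEL_VOCAB`, one per sequence.
#' @return an `NRDataset`.
#' @export
NRDataset <- function(sequences, labels) {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  new("NRDataset", sequences = sequences, labels = unname(as.character(labels)))
}

#' @describeIn NRDataset-class the sequences.
#' @param x,object an `NRDataset`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname NRDataset-class
#' @export
setMethod("sequences", "NRDataset", function(x) x@sequences)

#' @describeIn NRDataset-class per-sequence labels (`nonNR`, `NR1`..`NR0`).
#' @export
setGeneric("subfamilyLabels", function(x) standardGeneric("subfamilyLabels"))

#' @rdname NRDataset-class
#' @export
setMethod("subfamilyLabels", "NRDataset", function(x) x@labels)

#' @describeIn NRDataset-class binary level-1 labels (`NR` vs `nonNR`).
#' @export
setGeneric("level1Labels", function(x) standardGeneric("level1Labels"))

#' @rdname NRDataset-class
#' @export
setMethod("level1Labels", "NRDataset", function(x) ifelse(x@labels == "nonNR", "nonNR", "NR"))

#' @rdname NRDataset-class
#' @export
setMethod("length", "NRDataset", function(x) length(x@sequences))

#' @rdname NRDataset-class
#' @param i index vector.
#' @export
setMethod("[", "NRDataset", function(x, i) {
  new("NRDataset", sequences = x@sequences[i], labels = x@labels[i])
})

setMethod("show", "NRDataset", function(object) {
  cat(sprintf("NRDataset: %d sequences\n", length(object)))
  print(table(factor(object@labels, levels = LABEL_VOCAB)))
})

#' Read a FASTA file
#'
#' Parses the standard dialect: records start at lines whose first column is
#' `>`; subsequent lines up to the next `>` are concatenated into the
#' sequence. The sequence id is the first whitespace-delimited token of the
#' header; the full header is kept as a `headers` attribute. Malformed input
#' (content before the first `>`, an empty sequence block, an empty header)
#' is an error that reports the offending line number. CRLF endings are
#' tolerated.
#'
#' @param path file path or character vector of lines (`textConnection`-free
#'   convenience for tests).
#' @return `AAStringSet` named by sequence id, with attribute `headers`
#'   holding the full header lines.
#' @export
readFasta <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("\r$", "", lines)
  isHdr <- startsWith(lines, ">")
  nonEmpty <- nzchar(trimws(lines))
  if (!any(isHdr))
    pcStop("MalformedFasta", "no FASTA records found (no line starts with '>')")
  first <- which(isHdr)[1L]
  junk <- which(nonEmpty[seq_len(first - 1L)])
  if (length(junk))
    pcStop("MalformedFasta",
           sprintf("line %d: sequence content before the first '>' header", junk[1L]))
  hdrIdx <- which(isHdr)
  blockEnd <- c(hdrIdx[-1L] - 1L, length(lines))
  headers <- character(length(hdrIdx))
  seqs <- character(length(hdrIdx))
  for (k in seq_along(hdrIdx)) {
    h <- trimws(sub("^>", "", lines[hdrIdx[k]]))
    if (!nzchar(h))
      pcStop("MalformedFasta", sprintf("line %d: empty FASTA header", hdrIdx[k]))
    body <- lines[seq(hdrIdx[k] + 1L, length.out = blockEnd[k] - hdrIdx[k])]
    s <- gsub("[[:space:]]", "", paste(body, collapse = ""))
    if (!nzchar(s))
      pcStop("MalformedFasta", sprintf("line %d: record '%s' has an empty sequence", hdrIdx[k], h))
    headers[k] <- h
    seqs[k] <- s
  }
  ids <- vapply(strsplit(headers, "[[:space:]]+"), `[[`, character(1L), 1L)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  attr(out, "headers") <- headers
  out
}

#' Write sequences to FASTA
#'
#' Output wraps sequence lines at 60 columns.
#'
#' @param seqs `AAStringSet` or named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a label manifest
#'
#' Two-column tab-separated text: sequence id, label from `LABEL_VOCAB`.
#' Lines starting with `#` and blank lines are ignored; an optional header
#' line `id<TAB>label` is skipped. Unknown labels and duplicate ids are
#' errors reporting the offending line number.
#'
#' @param path file path or character vector of lines.
#' @return named character vector of labels, names = sequence ids.
#' @export
readManifest <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  ids <- character(0); labs <- character(0); seen <- character(0)
  for (ln in idx) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      pcStop("UnknownLabel", sprintf("line %d: expected two tab-separated columns", ln))
    id <- trimws(parts[1L]); lab <- trimws(parts[2L])
    if (ln == idx[1L] && identical(tolower(c(id, lab)), c("id", "label"))) next
    if (!(lab %in% LABEL_VOCAB))
      pcStop("UnknownLabel", sprintf("line %d: unknown label '%s'", ln, lab))
    if (id %in% seen)
      pcStop("DuplicateId", sprintf("line %d: duplicate sequence id '%s'", ln, id))
    seen <- c(seen, id)
    ids <- c(ids, id); labs <- c(labs, lab)
  }
  if (length(ids) == 0L)
    pcStop("UnknownLabel", "manifest contains no entries")
  stats::setNames(labs, ids)
}

#' Write a label manifest
#'
#' @param labels named character vector (names = ids) or an [NRDataset-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(labels, path) {
  if (is(labels, "NRDataset"))
    labels <- stats::setNames(subfamilyLabels(labels), names(sequences(labels)))
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  invisible(path)
}

#' Join sequences with a label manifest into a labeled dataset
#'
#' In strict mode (default) every manifest id must be present among the
#' sequences and vice versa; in intersection mode the common ids are kept
#' with a warning. Dataset order follows the FASTA record order.
#'
#' @param seqs `AAStringSet` from [readFasta()].
#' @param manifest named label vector from [readManifest()].
#' @param strict logical; if `FALSE`, keep the id intersection.
#' @return an [NRDataset-class].
#' @export
joinDataset <- function(seqs, manifest, strict = TRUE) {
  ids <- names(seqs)
  missingSeq <- setdiff(names(manifest), ids)
  missingLab <- setdiff(ids, names(manifest))
  if (strict && (length(missingSeq) || length(missingLab))) {
    if (length(missingSeq))
      pcStop("MissingSequence",
             sprintf("manifest ids with no sequence: %s", paste(missingSeq, collapse = ", ")))
    pcStop("MissingSequence",
           sprintf("sequences with no label: %s", paste(missingLab, collapse = ", ")))
  }
  common <- ids[ids %in% names(manifest)]
  if (!strict && length(common) < max(length(ids), length(manifest)))
    pcWarn("PartialJoin",
           sprintf("intersection mode: kept %d of %d sequences", length(common), length(ids)))
  if (length(common) == 0L)
    pcStop("MissingSequence", "no sequence ids match the manifest")
  NRDataset(seqs[common], manifest[common])
}
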