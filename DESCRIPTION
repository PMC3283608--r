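Package: PhysChemAAC
Title: Physicochemical Auto-Cross-Covariance Encoding and Two-Level SVM
    Classification of Nuclear Receptor Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein sequences as fixed-length pseudo amino acid
    compositions built from ten standardized physicochemical property scales
    via auto-covariance and cross-covariance transforms (1000 components at
    the default lag of 10), and classifies them with a two-level radial basis
    function support vector machine: level one separates nuclear receptors
    (NRs) from non-NRs, level two assigns predicted NRs to one of seven
    subfamilies (NR1-NR6, NR0). Includes grid-search hyperparameter selection
    under stratified cross-validation, jackknife and k-fold evaluation with
    per-class accuracy and Matthews correlation coefficients,
    leave-one-property-out impact ranking of the ten scales, FASTA and label
    manifest input/output, and a seeded synthetic-sequence generator with
    controllable class separation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
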