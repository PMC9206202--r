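Package: phenossu
Title: Deep Phenotyping of Clinical Text by Linguistic Pattern Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structures phenotype descriptions in clinical free text into
    entity-attribute-value (PhenoSSU) instances. Text is encoded as a
    single-letter sequence over a small alphabet (phenotype, attribute,
    punctuation, specimen, analyte, number, unit, result word, other),
    recurring linguistic patterns are discovered with an expectation-
    maximization motif finder on the encoded sequences, motifs are reduced
    to a regular-expression pattern library, and instances are recognized
    by scanning encoded text with the library. Includes normalization of
    quantitative lab results against reference ranges, exact-span and
    attribute-level evaluation metrics, brat standoff input/output, and a
    synthetic annotated-corpus generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
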