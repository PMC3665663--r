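Package: pathconcord
Title: Concordance Analysis for Pairs of Metabolic Pathway Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for reconciling and comparing the compound, reaction and
    pathway content of two metabolic pathway databases. Provides a
    BioCyc-style attribute-value flat-file data model, rule-based compound
    correspondence inference (structure-key and fingerprint Tanimoto
    features, exact stereo-structure matching, all-but-one substrate
    inference), stoichiometric-matrix cosine reaction matching with an
    EC-number fallback, reaction mass-balance auditing with and without
    hydrogen, overlap and coverage statistics with Jaccard coefficients,
    binomial audit-sampling accuracy estimation with Clopper-Pearson
    intervals, Fisher-exact enrichment and depletion over a pathway-class
    ontology, and a seeded synthetic twin-database generator with known
    ground truth for end-to-end evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
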