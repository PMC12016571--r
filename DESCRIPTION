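Package: npsite
Title: Prediction and Characterization of Protein N-Phosphorylation Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for protein N-phosphorylation (pHis, pLys, pArg) site
    analysis. Builds benchmark datasets from curated phosphosite annotation
    tables using solvent-accessibility and sequence-identity filters, encodes
    phosphosite-centered 31-residue peptide windows as amino-acid composition,
    AAindex HQI8 physicochemical, and BLOSUM62 row features, trains
    gradient-boosted decision-tree classifiers with repeated hold-out and
    cross-validated evaluation, computes enrichment (E-ratio) and motif-x
    style motif statistics, scans FASTA proteomes for candidate sites with
    reliability grading, and generates seeded synthetic proteomes with
    planted sequence signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
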