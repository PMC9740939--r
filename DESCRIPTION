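Package: herbipk
Title: Integrated Multi-Component Pharmacokinetics with Bioanalytical
    Validation and Offline Network Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental pharmacokinetic (NCA) analysis of
    multi-analyte plasma concentration-time data, AUC-proportional
    weighting of component profiles into a single integrated profile with
    NCA on the result, bioanalytical method-validation statistics
    (weighted calibration, precision/accuracy, extraction recovery,
    matrix effect, regulatory acceptance windows), and an offline
    network-pharmacology stage (target intersection, degree/closeness
    topology, key-target selection, hypergeometric pathway enrichment
    with Benjamini-Hochberg correction).  Includes a synthetic study
    generator producing study-shaped plasma, quality-control and
    target/pathway datasets with known ground truth, and an end-to-end
    pipeline driver with file readers/writers for the long-format CSV,
    TSV, GMT and SIF dialects used by the analysis stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
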