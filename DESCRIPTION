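Package: cfcin
Title: Chromosomal Instability Scoring from Low-Coverage Cell-Free DNA
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a quantified chromosome-instability (CIN) score from
    binned low-coverage whole-genome sequencing of plasma cell-free DNA.
    Coverage is counted in fixed genomic bins, Z-normalized against a panel
    of healthy controls, segmented by circular binary segmentation with
    permutation significance, and summarized as log2 of the sum of segment
    value times segment length in 200-kb units. Includes classification of
    samples at a CIN cutoff, cohort arm-level gain/loss frequencies, the
    survival statistics used to validate the score (Kaplan-Meier, log-rank,
    Cox proportional hazards, time-horizon survival ROC with Youden cutoff
    selection, Fisher exact tests), a synthetic-data generator for planted
    copy-number events and proportional-hazards survival cohorts, and a
    reproducible per-sample and cohort pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Rsamtools,
    GenomicRanges,
    IRanges,
    survival,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
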