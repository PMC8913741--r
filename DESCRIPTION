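Package: ppikit
Title: Paired Alignments, Interface Metrics and Confidence Scores for
    Predicted Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for preparing inputs to, and assessing outputs of,
    structure predictors applied to heterodimeric protein complexes.
    Builds paired and block-diagonalized multiple sequence alignments
    from per-chain a3m files using organism (OX) matching, estimates
    alignment depth as an effective sequence count (Neff) by greedy
    clustering at 62% identity, extracts interface contact and
    confidence (plDDT) metrics from two-chain PDB models, computes and
    re-fits the pDockQ sigmoid confidence score, scores models against
    native structures with a self-contained DockQ implementation
    (Fnat, iRMS, LRMS), and provides the associated evaluation
    calculus: ROC/AUC, PPV/FDR, success rate, top-N coupling-signal
    precision, secondary-structure interface classes and tertile
    binning.  Seeded synthetic-fixture generators make the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
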