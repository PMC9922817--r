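Package: mitopulse
Title: Pulse-SILAC Analysis of Mitochondrial Translation and OXPHOS Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pulse stable-isotope labeling (pSILAC) proteomics of
    mitochondrial translation: in-silico protease digestion and observable
    peptide / iBAQ accounting, a generative first-order turnover model of
    three-channel SILAC evidence with known ground truth, peptide-to-protein
    H/M ratio quantification with empirical-Bayes moderated statistics,
    pulse-chase degradation scoring with CAP-sensitivity classification,
    OXPHOS complex and subcomplex summaries, and Fisher/Benjamini-Hochberg
    term enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    limma,
    deSolve,
    jsonlite
Config/testthat/edition: 3
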