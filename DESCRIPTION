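Package: homoeoExpr
Title: Homoeolog-Specific Expression from Parent-Specific Array Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of parent-specific array features (PSFs) on short-oligo
    expression arrays and their use to measure homoeolog-specific gene
    expression in allopolyploids. Implements probe-level additive linear
    models with SAM d-statistics and permutation-calibrated thresholds for
    PSF discovery, E_p/E_t intensity-ratio estimation of parental genome
    contributions, 1:1 and 1:2 mid-parent dosage contrasts under
    Benjamini-Hochberg FDR control, sequence- and RNA-mix-based validation,
    qPCR R0 quantification, category enrichment statistics, and a
    probe-level simulator with known ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
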