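Package: neomarker
Title: Tissue and Plasma Biomarker Discovery and Validation for Colorectal Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering and validating colorectal
    neoplasia RNA biomarkers. Implements per-probeset two-sample differential
    expression across phenotype contrasts (normal, IBD, adenoma, cancer) with
    Bonferroni or Benjamini-Hochberg correction and fold-change filtering, a
    background-threshold "switched-on/switched-off" caller for
    phenotype-specific transcripts based on the 30th percentile of per-probeset
    mean intensities, discovery-to-validation candidate translation and
    directional concordance reporting, and quantitative PCR analysis: Livak
    comparative-threshold (2^-ddCt) relative quantification for tissue assays,
    armored-RNA spike-in normalization and fold change versus the control-group
    median for plasma assays, detection calls, an exact Mann-Whitney test, and
    a penalized logistic cycle-threshold classifier. A synthetic-data module
    generates expression cohorts and qPCR panels with planted ground truth so
    every stage is testable end to end.
License: GPL-3
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
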