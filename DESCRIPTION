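Package: isribtools
Title: Screen Scoring, Co-Fractionation, Exchange Kinetics and Potency
    Analysis for ISR Inhibitor Target Identification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the multi-pronged analysis that
    identifies eIF2B as the cellular target of ISRIB-class integrated
    stress response inhibitors: scoring of pooled FACS-sorted shRNA
    screens with an empirical negative-control null (per-shRNA log2
    enrichment phenotypes and gene-level Mann-Whitney tests),
    co-fractionation correlation profiling of sucrose-gradient mass
    spectrometry with Svedberg calibration, first-order GDP-dissociation
    kinetics with bootstrap uncertainty, and four-parameter logistic
    dose-response fitting with a substituent-additivity model for
    structure-activity analysis. Includes synthetic-data generators that
    emulate each raw data family under presets traceable to published
    experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
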