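Package: glycopd
Title: Plasma and IgG N-Glycome Case-Control Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-cohort case-control analysis of HILIC-UPLC
    N-glycomics data, as applied in studies of chronic obstructive pulmonary
    disease (COPD). Covers glucose-unit calibration and fixed-window peak
    integration of chromatograms, total-area normalisation, log
    transformation and empirical-Bayes (ComBat) batch correction, derived
    glycan trait computation for the 39-peak total plasma and 24-peak IgG
    N-glycome panels, rank-based inverse-normal transformation,
    covariate-adjusted logistic and linear association models fitted per
    cohort, inverse-variance random-effects meta-analysis and
    Benjamini-Hochberg false-discovery-rate control. A synthetic-data
    generator emulates the two-cohort study design with known injected
    effects and batch artifacts so the full pipeline can be exercised and
    calibrated without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sva,
    metafor,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
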