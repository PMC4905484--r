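Package: plasmaMiR
Title: Two-Phase Plasma microRNA Biomarker Discovery and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circulating microRNA qPCR biomarker studies
    in colorectal cancer. Implements stability-based selection of endogenous
    normalization references from TaqMan array cycle-threshold (Ct) data,
    delta-delta-Ct relative quantification against endogenous or spike-in
    (cel-miR-39) controls, marker screening across seven staged group
    comparisons, logistic/ROC marker evaluation with Hanley-McNeil standard
    errors and Youden cutoffs, and mean-dichotomized Kaplan-Meier, log-rank and
    Cox proportional-hazards survival analysis. A synthetic-cohort generator
    emulates a two-phase discovery (50 samples x 754 assays) and validation
    (234 samples) study design with planted marker effects and a machine
    readable ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
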