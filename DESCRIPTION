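Package: sputumFlow
Title: Automated Gating and Diagnostic Classification of Sputum Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated analysis pipeline for multi-tube sputum flow
    cytometry aimed at lung cancer detection. Reads FCS event data, derives
    spillover compensation de novo from single-stain controls, applies the
    logicle (biexponential) transform, removes flow-rate anomalies, and runs a
    heuristics-guided gating cascade (bead-anchored size exclusion, corner
    artifact removal, density tail-gated viability, and a singlets polygon
    with automatic repair) to isolate viable single cells. From viable
    singlets it extracts per-10,000 quantized features (fluorescence-to-
    scatter density regions and 4x4 intensity grids), fits and applies a
    logistic cancer/non-cancer classifier with stepwise predictor selection
    and ROC-based cutoff choice, and reports diagnostic accuracy statistics
    (Wilson confidence intervals, prevalence-adjusted predictive values,
    positive diagnostic likelihood ratio, bootstrap AUC). A synthetic sample
    and cohort generator with per-event ground truth makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mclust,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
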