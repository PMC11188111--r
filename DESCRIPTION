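Package: restfc
Title: Linking In-Scanner Experience Reports to Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline relating retrospective in-scanner experience
    reports to resting-state functional connectivity (FC). Implements bounded,
    confound-aware questionnaire factorization with data-driven hyperparameter
    selection; agglomerative grouping of scans into thought-pattern sets with
    within-subject consistency and confound-matching checks; FC construction
    from ROI time series with motion-based volume censoring; the Network-Based
    Statistic (edge-level GLM, suprathreshold connected components,
    permutation family-wise error control of component extent); and
    connectome-based predictive modeling with grouped cross-validation,
    permutation significance and consensus-edge extraction. A seeded synthetic
    data module generates questionnaire, demographic, motion and connectivity
    data with planted effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
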