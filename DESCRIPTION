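Package: myosignal
Title: Kinase Activity, Substrate Prediction and Temporal Event Ordering
    for Time-Resolved Phosphoproteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for analysing time-resolved and inhibitor-perturbed
    phosphoproteome and proteome quantification matrices. Implements
    left-censoring-aware two-stage imputation, filtering, ratio conversion,
    batch correction and control-feature normalisation; substrate-set kinase
    activity inference on standardized contrasts with direction-based
    integration of paired inhibitor contrasts; kinase-substrate prediction
    from position-specific scoring matrices combined with temporal
    phosphorylation profiles, signalome network construction and
    inhibitor-specificity dissection; enrichment-guided temporal clustering
    with event ordering; moderated t-tests with empirical-Bayes variance
    shrinkage and dynamic-regulation calls; and cross-omics concordance
    utilities. Ships a synthetic-data generator with planted ground truth
    (kinase activities, motifs, substrates, pathways, batch effects,
    missingness) so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite
Config/testthat/edition: 3
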