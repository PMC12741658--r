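Package: somnalign
Title: Multimodal Sleep Measurement Derivation and Cross-Modal Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives nightly sleep onset, offset and total sleep time from four
    heterogeneous raw streams -- 30-second actigraphy epoch labels, 1 Hz
    ballistocardiographic bed-sensor status codes, smartphone screen lock/unlock
    events and categorical morning self-reports -- using 3 PM-to-3 PM study
    windows, 5-minute gap merging, longest-episode selection and plausibility
    filtering. Quantifies agreement between measurement modalities with
    Bland-Altman bias and limits of agreement, paired t tests and Pearson
    correlations with Fisher-z intervals, and models day-level absolute
    between-modality differences with linear mixed models including
    demographic, chronotype, diagnostic-group and seasonal day-length
    predictors (variance components, ICC, marginal and conditional R2). Ships a
    synthetic cohort generator with known ground truth, group-dependent sleep
    timing, device-specific biases, missingness and seasonal daylight
    modulation, so the full pipeline is testable without access to raw study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
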