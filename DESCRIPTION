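Package: tssrisk
Title: Targeted Surgical Score for Mechanical Complication Risk After
    Proximal Femoral Nailing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes the targeted surgical score (TSS), a 0-8 point
    radiographic score summarising implant placement and fracture
    reduction quality after proximal femoral nailing of intertrochanteric
    femur fractures: magnification-corrected tip-apex distance,
    Cleveland-Bosworth lag-screw quadrant, collo-diaphyseal angle
    difference, lateral angulation, and medial/anterior cortical support.
    Provides the scoring rules, clinical risk bands, a logistic model of
    mechanical complications on the score with Wald inference, odds
    ratios, ROC/AUC and Youden cutoff selection, Hosmer-Lemeshow
    calibration, McFadden pseudo R-squared, likelihood-ratio, rank-based
    and proportion tests, and a moment-matched Gaussian-copula synthetic
    cohort generator calibrated to published group summaries, so the
    whole analysis can be exercised without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
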