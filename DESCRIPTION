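Package: histrisk
Title: Weakly Supervised Survival Risk Prediction from H&E Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains convolutional risk predictors on haematoxylin-and-eosin
    (H&E) tissue image tiles using only patient-level right-censored survival
    data, i.e. without any region-level annotations. Provides Otsu tissue
    segmentation and overlapping-tile enumeration for slide images, the Cox
    negative log partial likelihood as a training loss with unique-patient
    mini-batching, a compact convolutional backbone with parameter-free
    spatial and channel attention gating, patient-level risk aggregation by
    the median tile risk, risk density map overlays, and a survival
    evaluation stack (Harrell's concordance index, Kaplan-Meier curves,
    log-rank tests, univariable and multivariable proportional-hazards
    regression with hazard ratios). A synthetic H&E-like slide and cohort
    generator with per-pixel ground-truth informativeness maps makes the
    whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    survival,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
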