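Package: hrvrisk
Title: Heart-Rate-Variability Risk Stratification After Acute Myocardial
    Infarction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of time-domain heart-rate-variability indices,
    heart-rate turbulence, and phase-rectified signal averaging
    (deceleration and acceleration capacity) from 24-hour RR-interval
    tachograms, and risk stratification of post-infarction cardiac death
    with support-vector-machine models evaluated by leave-one-out
    cross-validation. Includes a synthetic-cohort simulator (feature-level
    class-conditional cohorts and signal-level RR tachograms with
    injectable ground-truth ectopy and turbulence), ROC/AUC evaluation
    with DeLong comparison of correlated curves, and single-index
    threshold comparators (SDNN, deceleration capacity, LVEF).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    MASS,
    pROC,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
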