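Package: frphrv
Title: Fuzzy Recurrence Plot Analysis of Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects slow-paced-breathing relaxation states from RR-interval
    (heart rate variability) recordings. Converts tachograms into fuzzy
    recurrence plot images via fuzzy C-means clustering and max-min fuzzy
    relation composition, extracts 39 features across five domains (time,
    frequency, Poincare geometry, entropy, and grey-level co-occurrence
    texture), screens them with paired nonparametric statistics and
    rank-biserial effect sizes, reduces them through a Fisher discriminant
    ratio / correlation / greedy-stepwise cascade, and evaluates six standard
    classifiers under stratified cross-validation. Includes a synthetic
    paced-breathing RR simulator with respiratory sinus arrhythmia so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    class,
    e1071,
    nnet,
    randomForest,
    rpart,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Collate:
    'utils.R'
    'rr-series.R'
    'simulate.R'
    'hrv-classic.R'
    'entropy.R'
    'fcm.R'
    'frp.R'
    'glcm.R'
    'features.R'
    'stats-effects.R'
    'selection.R'
    'classify.R'
    'pipeline.R'
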