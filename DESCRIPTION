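Package: wvgerp
Title: Weighted Visibility Graph Analysis and Ensemble Classification of ERP Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multichannel event-related potential (ERP) epochs into
    weighted visibility graphs, extracts graph-topological features per
    channel, frequency band and task condition, and discriminates two subject
    groups with leakage-safe feature selection (training-set t-tests followed
    by PCA) and a majority-vote ensemble of classifiers trained on
    non-overlapping trial subgroups. Includes a synthetic two-group ERP cohort
    generator with N400/P600-like components so the full pipeline can be
    exercised and calibrated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    class,
    e1071,
    randomForest,
    pROC,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
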