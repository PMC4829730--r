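Package: moodstep
Title: Personalized Mood Prediction from Smartphone Usage Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting day-to-day self-reported
    mood from unobtrusively logged smartphone usage. Provides a configurable
    synthetic generator of per-participant phone-log event streams (calls,
    SMS, screen, apps, camera, accelerometer activity) and mood diaries; the
    53-variable daily feature engineering used in personalized digital
    phenotyping studies (top-contact interaction histograms over a sliding
    window, screen-use statistics, app-category histograms, photo counts,
    mood-history lags); personalized forward stepwise regression driven
    either by PRESS-based leave-one-out cross-validated error or by AIC,
    with a training-size-dependent complexity cap; naive benchmark models
    (intercept-only mean model and a lag-2 history model); and an evaluation
    framework covering full-data leave-one-out assessment with a tolerated
    error margin, Wilcoxon signed-rank benchmark comparisons, and an
    incremental growing-training-window assessment with a trend regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
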