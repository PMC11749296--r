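Package: pbhcast
Title: Short-Term Forecasting of Post-Bariatric Hypoglycaemia from CGM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting post-bariatric hypoglycaemia (PBH) from
    continuous glucose monitoring (CGM) data alone. Provides causal CGM
    preprocessing (5-minute grid alignment, gap interpolation for training
    data, zero-order-hold filling for real-time use), a family of
    multi-step glucose forecasters built around a recursive autoregressive
    model with exponential forgetting, predictive hypoglycaemia alarms
    with a shut-off rule, event-based performance metrics (precision,
    recall, F1, false alarms per day, time gain, mean absolute error,
    glycaemic variability summaries including MAGE), grid-search tuning of
    the prediction horizon and alarm threshold, and a calibrated synthetic
    PBH-CGM simulator so the full pipeline can be exercised without
    patient data.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
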