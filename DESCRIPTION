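Package: lineuproc
Title: Signal Detection Simulation and ROC Analysis of Eyewitness Identification Procedures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of eyewitness identification procedures
    (showups, simultaneous lineups under absolute and relative decision rules,
    sequential lineups under first-identification and any-identification
    stopping rules, and two-alternative forced choice) from Gaussian
    signal-detection evidence models, together with the measurement toolkit
    used to compare them: empirical and analytic ROC curves, partial AUC with
    percentile bootstrap confidence intervals, the diagnosticity ratio and its
    confounding with response bias, and Bayesian posterior-of-guilt and
    information-gain curves over the target-present base rate. All simulation
    inputs are synthetic; confidence-binned count tables can also be supplied
    to build empirical ROCs.
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
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
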