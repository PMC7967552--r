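Package: alcpolicy
Title: Tiered Classification and Time-Series Evaluation of Alcohol Control Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing national alcohol control policies for
    quasi-experimental evaluation. Computes an alcohol affordability index
    from disposable-income and alcohol-price index series, classifies dated
    policy interventions into impact tiers using objective criteria
    (affordability change thresholds, scope of availability restrictions,
    target population, study-window power requirements), builds a cumulative
    policy-score step series, aggregates expert impact ratings with
    interrater-reliability statistics (intraclass correlation, Spearman rank
    agreement) for a sensitivity analysis, and fits segmented interrupted
    time-series regressions with step or lagged intervention effects,
    seasonal terms, economic covariates, and AR(1) error correction. A
    synthetic-data module generates economic series with prescribed
    affordability changes, monthly outcome series with known intervention
    effects, and expert rating matrices with controllable agreement, so the
    whole pipeline runs and is testable without external data.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
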