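Package: g1span
Title: G1 Cell-Size Control Kinetics and Replicative Lifespan Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the kinetic determinants of the budding-yeast G1
    phase (birth size, critical size, specific growth rate, G1 duration) from
    elutriation time courses and cell-volume histograms; quantification of
    cell-size-control efficiency as the slope of relative G1 growth against
    log birth size; first-order protein-decay half-life fitting from
    cycloheximide-chase densitometry; lifespan survival analysis including
    Kaplan-Meier curves, log-rank and Wang-Allison maximum-lifespan tests;
    and long-lived versus not-long-lived strain-panel comparisons with rank
    tests, Welch t tests and logistic-regression predictor ranking. Ships a
    seeded synthetic-data generator emulating every input so the full
    pipeline runs with no external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
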