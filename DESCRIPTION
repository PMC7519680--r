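Package: transmr
Title: Transient-Aware Capture-Mark-Recapture Models and Their Population
    Consequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting, estimating and projecting the demographic
    consequences of transient individuals in capture-mark-recapture (CMR)
    studies of breeding animals. Provides the directional goodness-of-fit
    test 3.SR and its companion 3.Sm, overdispersion (c-hat) estimation,
    maximum-likelihood Cormack-Jolly-Seber models with a transience
    probability structured by age at first breeding and an environmental
    (density-dependence) covariate, analysis of deviance (ANODEV) for
    covariate models, a synthetic encounter-history generator with a known
    truth record, and a transient-structured stage-based matrix population
    model with sensitivity, elasticity and fixed-design life table response
    experiment (LTRE) analyses, including a population-growth-rate response
    surface over density and transience.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
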