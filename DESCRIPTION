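Package: tillerscope
Title: Predicting Maize Tiller Density from Environment and Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for modelling tiller density in field maize as a
    function of environment and management. Derives agroclimatic covariates
    (growing degree days, photothermal quotient, cumulative vapour pressure
    deficit and moisture, temperature means, areal soil nutrient masses) from
    daily weather, soil characterisation and plot observations; fits binomial
    generalized additive models of the probability of attaining a maximum
    tiller density with factor-by thin-plate smooths over plant-density
    classes; ranks a registry of candidate models by held-out mean absolute
    error; validates out of season with coefficient-zeroing error attribution;
    and extracts non-limiting covariate thresholds as 0.50-probability
    crossings of response curves. Includes a seeded synthetic site-year
    generator with known ground truth so every stage is testable end to end.
License: MIT
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
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
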