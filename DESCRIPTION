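Package: paleodisp
Title: Climate-Forced Population Dispersal Modelling with Human Existence Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Niche-model-driven simulation of prehistoric population dispersal.
    Estimates human existence potential (HEP) from archaeological site
    presence/absence records and gridded bioclimatic predictors with an
    ensemble of quadratic logistic regressions validated by spatially blocked
    cross-validation (Brier skill score, AUC); transforms it into accessible
    and available HEP via terrain/water modifiers and a Weibull
    population-pressure response; and integrates an
    advection-diffusion-logistic population equation under stadial/interstadial
    isotope forcing to reconstruct dispersal chronologies, population sizes,
    mobility and flux networks, with perturbed-parameter ensembles for
    uncertainty quantification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    geosphere,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
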