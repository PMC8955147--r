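Package: filmkin
Title: Release Kinetics, IVIVC Convolution and Permeation Analysis for
    Mucoadhesive Buccal Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for fast-dissolving mucoadhesive films:
    closed-form evaluation and bounded nonlinear least-squares fitting of
    nine empirical drug-release models (zero order, first order, Higuchi,
    Korsmeyer-Peppas, Hixson-Crowell, Hopfenberg, Baker-Lonsdale,
    Peppas-Sahlin, Weibull) with adjusted R-squared, RMSE and AIC model
    ranking; convolution-based prediction of in-vivo plasma
    concentration-time profiles from in-vitro dissolution data using a
    polyexponential unit impulse response, with Cmax, Tmax and AUC
    extraction; Franz diffusion-cell permeation analysis with
    sampling-replacement correction, steady-state flux and apparent
    permeability estimation; film mechanics (tensile strength, percent
    elongation); and seeded synthetic-data generators so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
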