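Package: barngas
Title: Ammonia and Methane Concentration and Emission Modelling for
    Naturally Ventilated Dairy Barns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating and predicting ammonia (NH3) and methane
    (CH4) concentrations and emission rates in naturally ventilated dairy
    barns. Implements the indirect CO2 mass-balance method (CIGR-style
    heat-production equations, temperature correction, per-cow CO2
    excretion, ventilation rate and per-livestock-unit emission rates),
    behavioural indices (cow lying and activity indices) derived from
    15-minute scan sampling, model-ready dataset assembly with min/max
    normalisation and 70:15:15 partitioning, a from-scratch multilayer
    perceptron with tansig hidden units trained by Levenberg-Marquardt
    with early stopping, an incremental hidden-layer architecture search,
    and an input-variable ablation runner that ranks feature groups
    (climatic variables, animal activity, diet, gas concentrations) by
    predictive performance. A seeded synthetic barn-campaign generator
    with known ground truth makes every stage testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
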