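Package: ltbr
Title: Light-Time-Biomass Response Modelling for Indoor Seedling Production
Version: 1.0.0
Authors@R:
    person("Plant Factory Modelling", "Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for modelling the dry-weight growth of leafy-vegetable
    seedlings (developed around choy sum, Brassica rapa var. parachinensis)
    raised under white LED lighting in indoor plant factories. Provides
    closed-form candidate growth models in time and light intensity,
    Levenberg-Marquardt nonlinear least-squares fitting with full inference
    (parameter standard errors, t- and F-tests, R-squared, AIC), AIC-based
    model selection with an interpretability preference, assembly of a
    two-region piecewise light-time-biomass response surface, derived
    physiological indices (moisture content, productivity, relative growth
    rate, net assimilation rate, net photosynthetic rate, photosynthetic
    efficiency, spectral energy conversion), a validation protocol against
    replicated measurements, a regressor-substitution robustness test, and a
    seeded synthetic-data generator emulating the sextuplicate measurement
    design so the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
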