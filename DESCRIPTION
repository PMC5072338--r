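Package: circaflux
Title: Circadian Regulation of Leaf-to-Canopy Gas Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of circadian regulation in plant gas
    exchange from leaf to canopy scale. Provides a synthetic generator for
    Ecotron-style entrainment/free-running experiments, stomatal conductance
    models (Ball-Berry, Leuning, Medlyn) with an optional sinusoidal
    circadian oscillator on the slope parameter, AIC-based model selection
    with Akaike weights and calibration/validation splits, penalized-spline
    trend smoothing with AR(1) residuals and first-derivative significance
    analysis, quantification of clock-driven variation in flux ranges, and
    derivation of canopy fluxes from open-chamber CO2 mass balance and
    weighing-lysimeter records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
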