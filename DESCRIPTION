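Package: rubidyn
Title: Rubisco Activation Dynamics and Diurnal Assimilation Under Fluctuating Light
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Kinetic models of Rubisco regulation during sun-shade-sun
    transitions and their consequences for diurnal carbon gain. Fits
    piecewise exponential models of Rubisco activation state and of maximum
    carboxylation rate (Vc,max) recovery, computes closed-form deactivation
    time constants from shade endpoints, inverts the Farquhar-von
    Caemmerer-Berry Rubisco-limited rate to one-point Vc,max estimates from
    induction gas exchange, fits steady-state light and CO2 response curves
    (non-rectangular hyperbola; Ethier-type finite mesophyll conductance),
    and simulates diurnal assimilation under fluctuating canopy light to
    quantify assimilation foregone to slow Rubisco regulation. Includes
    seeded synthetic-data generators for every input so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
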