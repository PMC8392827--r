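Package: fermco2
Title: Temperature-Considered Dynamic Modelling of CO2 Production in
    Batch Milk Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic modelling of milk fermentation with kefir grains in a
    batch bioreactor, using dissolved CO2 as the observable fermentation
    product.  Provides the fundamental 3-state growth/substrate/product
    model with product inhibition, substrate saturation and substrate
    inhibition; a 4-state temperature-considered extension in which the
    bioreactor temperature follows a first-order lag toward the reference
    temperature of the heating system and scales the growth rate and the
    growth-associated yield linearly with the temperature deviation; a
    deSolve-based simulator with piecewise-constant temperature protocols;
    an integral-absolute-error (IAE) objective and a two-stage particle
    swarm optimization procedure that identifies the six kinetic and three
    temperature-coupling parameters from measured CO2 time courses; a local
    parameter-sweep sensitivity analysis with transient/steady-state impact
    classification; and a synthetic-experiment generator emulating the
    laboratory sampling and sensor-noise structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
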