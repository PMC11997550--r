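Package: coralbleach
Title: Single-Polyp Mechanistic Simulator of Temperature-Mediated,
    Light-Driven Coral Bleaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates oxidative stress and bleaching of the
    coral-Symbiodiniaceae symbiosis at the scale of a single polyp. The model
    couples photon absorption and partitioning through photosystem II reaction
    centres (oxidised, reduced, inhibited states), temperature-dependent
    RuBisCO inactivation, xanthophyll-cycle photoprotection, reactive oxygen
    species (ROS) generation and piecewise detoxification, Droop-style
    reserve-limited symbiont growth at Redfield stoichiometry, and
    ROS-threshold-gated symbiont cell expulsion. Includes a synthetic
    environmental-forcing generator (heat-hold temperature profiles, diel
    irradiance with prescribed daily light integrals, step-sampled nutrient
    series), the degree-heating-week thermal stress metric, scenario presets
    for a light by temperature factorial experiment, trajectory summaries and
    plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
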