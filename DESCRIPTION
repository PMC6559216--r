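Package: wheatideo
Title: Wheat Ideotype Design with a Daily Process-Based Crop Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs winter-wheat ideotypes for future climates. Combines a
    stochastic daily weather generator with climate-scenario morphing, a
    process-based daily wheat growth simulator (thermal-time phenology with
    vernalization and photoperiod, leaf-layer canopy and light interception,
    layered soil water balance, radiation-use-efficiency biomass production,
    heat and drought effects on grain set, grain filling with a labile
    carbohydrate pool), and an evolutionary search with self-adaptive
    mutation step sizes that optimizes eight cultivar traits for maximum,
    stable grain yield under rainfed and irrigated conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
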