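Package: algaescan
Title: Closed-System Scanning of Neural Forecasting Models for Algal Blooms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Early-warning forecasting of algal concentration and companion
    water-quality factors in lake source water. Implements an exhaustive
    scanning-focusing procedure that trains small feedforward neural networks
    over every subset of candidate factors and every hidden-layer size, with
    seeded replicate training, and selects "closed systems" - factor subsets
    in which every member improves whole-system forecasting and no outside
    factor adds improvement (a Granger-style retention rule). Includes a
    dilute-solution carbonate equilibrium solver for dissolved CO2 from pH,
    temperature and alkalinity, an alkalinity-from-conductivity regression
    with a nearest-in-time pairing rule, chlorophyll-equivalent risk banding
    for cell counts, and a synthetic lake-sensor scenario generator with a
    planted dependency structure so the whole pipeline is testable without
    restricted utility data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
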