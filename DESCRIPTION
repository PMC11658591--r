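Package: locustsim
Title: Integrated Simulation of Desert Locust Breeding, Development and
    Wind-Borne Swarm Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A spatially explicit, stochastic simulator of gregarious
    desert locust (Schistocerca gregaria) population dynamics and
    large-scale dispersal. Combines a random-forest breeding-suitability
    map trained on presence/absence survey records, temperature-driven
    egg and hopper development with biological viability windows,
    NDVI-based vegetation processing (Whittaker smoothing, piecewise
    trend segmentation, peak detection) and feeding-capacity rules, and
    swarm migration along pre-computed wind-trajectory ensembles with
    daily flight windows and coastline stopping. Includes a synthetic
    environment generator producing terrain, weather, NDVI, survey and
    trajectory fixtures, ensemble risk mapping (arrival dates, visit
    fractions), a short-term forecast backtracking filter, and von Mises
    characterisation of trajectory headings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    optparse
Config/testthat/edition: 3
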