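Package: dietsim
Title: Simulation-Based Integrated Assessment of Dietary Patterns
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic generator of individual-level dietary intakes across
    four archetypal dietary patterns (Mediterranean, Western, Plant-based,
    Mixed) with Dirichlet food-group composition sampling, nutrient and
    environmental-footprint aggregation from a food-group composition
    database, random-forest pattern classification with Gini importances,
    nutrient-adequacy regression, PCA and t-SNE latent-structure analysis,
    EAR cut-point adequacy prevalence, bootstrap uncertainty quantification,
    constrained tri-objective (adequacy, footprint, cost) diet optimization
    via NSGA-II with an exhaustive grid oracle, intervention scenario
    modelling, and benchmark validation against published reference tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    ranger,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
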