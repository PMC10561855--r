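Package: gapflux
Title: Individual-Based Daily Simulation of Forest Carbon Budgets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the daily carbon exchange of forest stands with an
    individual-tree gap-model structure: big-leaf light-response canopy
    photosynthesis with carbon dioxide, temperature, soil-water and nitrogen
    modifiers; per-tree maintenance and growth respiration routed through a
    nonstructural photosynthate buffer; ten-pool litter and soil organic
    matter decomposition with temperature and moisture rate modifiers and
    lignin shielding; annual allocation of buffered assimilate to tree
    structure through allometric relations; spin-up of the soil state to
    equilibrium; and aggregation of net ecosystem productivity (NEP) across
    forest types with relative-contribution accounting.  A seeded synthetic
    generator supplies daily weather, soil and vegetation inputs with
    realistic seasonal and autocorrelation structure, and evaluation
    utilities compare simulated NEP with eddy-covariance net ecosystem
    exchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
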