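Package: rcfopt
Title: Multi-Objective Spatial Optimization of Residential Care Facility
    Configuration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for configuring residential care facilities (RCFs) in an
    urban district: gravity-model spatial accessibility with distance decay,
    four stakeholder objectives (equity of accessibility, configuration
    efficiency, travel cost of the elderly, investor profit) scalarized with
    an adaptive penalty, and a modified immune algorithm (clonal selection
    with a variable selection threshold, elite recombination mutation,
    periodic mutation probability and global-best perturbation) that selects
    facility sites, sizes beds to demand and allocates population centers.
    Includes textbook genetic-algorithm, particle-swarm and immune-algorithm
    baselines over the same encoding, a three-step planning workflow
    (rationality assessment, relocation and bed adjustment, siting of new
    facilities), equity metrics (Gini coefficient, accessibility ratios), a
    seeded synthetic district generator, and GeoJSON/CSV/YAML interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
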