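Package: reservemax
Title: Multi-Objective Maximin Prioritization for Protected-Area Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and solves integer linear programs for systematic
    conservation planning on unit-based landscapes: single-objective
    reserve selection under an area budget, maximin multi-objective
    prioritization with elastic minimum-area constraints, minimum-area
    coverage of per-sub-population habitat targets, and habitat-target
    prioritization with an area-expansion penalty. Includes per-unit
    conservation-value layers (habitat area, species richness, an inverse
    Berger-Parker taxonomic index, range-restricted species, climate
    refugia, soil carbon), a seeded synthetic hexagonal-landscape
    generator for testing, trade-off reporting across objectives, and
    Jaccard overlap permutation tests between priority-area selections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
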