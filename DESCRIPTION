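Package: landsust
Title: Habitat-Loss Scenarios, Metapopulation Simulation and Multi-Criteria
    Ranking for Urban Landscape Sustainability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for comparing urban habitat-loss futures. Generates
    scenario landscapes by six patch-removal/shrinkage rule sets, builds
    species-specific habitat maps, downscales coarse grid-cell occurrence
    records to patch-level occupancy starting conditions, fits and simulates
    the classic incidence function metapopulation model, computes ecological
    and social sustainability measures, ranks scenarios with a PROMETHEE-style
    outranking analysis gated by Mann-Whitney tests, and detects habitat-loss
    thresholds in occupancy curves. Includes a synthetic landscape and
    occupancy generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
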