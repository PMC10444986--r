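Package: florivis
Title: Floral Resource Availability and Pollinator Visitation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies per-area nectar-sugar and pollen availability from
    field measurements of flowering communities, computes species
    contributions to floral resource provision and to insect visits,
    fits generalized additive models of seasonal trends, and compares
    Shannon diversity of resource-supplying versus insect-visited
    flowering species. Includes a seed-deterministic synthetic survey
    generator emulating a two-year riparian plant-pollinator study, so
    the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    mgcv,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
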