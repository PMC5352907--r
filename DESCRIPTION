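Package: climvuln
Title: Local Climate-and-Health Environmental Public Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building local climate-and-health environmental public
    health indicators for a rural multi-county health district. Detects hazard
    exposure events from daily weather and weekly drought-category series
    (extreme heat runs, heavy-precipitation days, severe-drought spells, and
    heat-drought overlap), classifies county indicators into high, moderate and
    low vulnerability tiers against state, national and federal-standard
    references, assembles the per-county hazard-by-indicator matrix with summary
    counts, and evaluates syndromic surveillance triggers and reportable-outcome
    matching over ICD-coded health records. Includes a synthetic-data module
    that generates weather, drought, indicator and claims inputs with known
    embedded structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    yaml,
    jsonlite,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
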