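Package: marginshift
Title: Range-Margin Dynamics and Realized Thermal Niche Limits from
    Breeding-Season Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives geographic range-margin and realized thermal-niche
    metrics for breeding birds from survey-route occurrence and abundance
    records combined with gridded monthly temperatures. Range margins are
    the k latitude-extreme occupied routes per multi-year period, realized
    thermal niche limits the k thermally extreme occupied routes, both
    summarized by abundance-weighted mean breeding-season (April-June)
    temperature within a 20-km buffer of each route centroid. Provides
    between-period margin displacement and per-decade shift rates,
    environmental distances between margins and niche limits, ordinary
    least-squares, paired-t and logistic-regression analyses of margin
    tracking and marginal-population extinction, supplementary fixed-site
    abundance-change analyses, and a virtual-ecologist generator of
    synthetic survey observations and climate grids with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
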