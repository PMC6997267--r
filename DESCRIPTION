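Package: geofoot
Title: Small-Area Hot-Spot Mapping of Diabetic Foot Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Small-area spatial epidemiology of diabetic foot disease:
    per-data-zone crude prevalence and incidence rates for foot ulceration,
    lower-extremity amputation and associated mortality; Getis-Ord Gi* local
    hot/cold-spot detection under a hybrid fixed-distance-band plus
    queen-contiguity spatial weights model; and one-sample chi-square tests of
    spot concentration across multiple-deprivation quintiles. Includes a
    synthetic-geography and cohort simulator (Voronoi data zones, spatially
    autocorrelated deprivation surface, deprivation-graded and spatially
    planted outcome risks) so the whole pipeline runs and is testable without
    access to linked health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    Matrix,
    jsonlite,
    foreign,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
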