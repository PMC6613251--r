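Package: abode
Title: Housing-Unit-Level Population Allocation Around Point Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Disaggregates census-block populations to geocoded residential
    housing units (ABODE, allocation by occupied domicile estimation) and
    compares the result with conventional proportional population allocation
    (PPA, areal weighting) for estimating nighttime residential populations
    inside radial hazard zones such as 200 m well areas and state surface
    setback distances. Includes dasymetric censoring of candidate dwelling
    points against a gridded land-use classification, planar geometry
    utilities (local equal-area projection, buffering, clipping, dissolving),
    model-agreement metrics (FAC2, MAPE, Spearman, fractional bias, Wilcoxon
    signed-rank), a seeded synthetic-region generator with per-dwelling
    ground truth, and report tables summarising population at risk by state.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    polyclip,
    sp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    optparse
Config/testthat/edition: 3
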