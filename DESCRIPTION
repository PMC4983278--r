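Package: stemflowS
Title: Sulfur Recovery Modelling from Beech Stemflow Micro-Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models recovery of forest soils from historic acid (sulfur)
    deposition using the micro-spatial heterogeneity of soil columns downhill
    of a beech stem. Routes stand-level stemflow sulfur through per-column
    infiltration areas, constructs delayed piecewise-linear annual input and
    output trajectories, detects the year each column turns from net sulfur
    source to net sink, and sweeps historic-load scenarios. Companion
    soil-chemistry tools compute element stores per distance and horizon,
    distance gradients, survey-to-survey pH and cation deltas, the depth of
    the acidification front, and inverse-distance-weighted pH maps. A seeded
    synthetic-data generator emulates the gradient structure these analyses
    assume so every step is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
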