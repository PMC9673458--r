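Package: plfcm
Title: Probabilistic Linguistic Fuzzy Cognitive Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fuzzy cognitive maps whose concept states and edge weights are
    probabilistic linguistic term sets (PLTSs). Provides the PLTS data model
    (normalisation, equivalent transformations, arithmetic, Euclidean distance
    and Z-mapping similarity measures), a two-channel (membership and
    probability) inference engine with a hyperbolic-tangent threshold and
    fixed-point / limit-cycle / chaotic terminal classification,
    similarity-based ranking of causal factors against an outcome concept,
    sensitivity analyses over the Z-mapping form and the threshold steepness,
    and two degenerate baselines (hesitant fuzzy linguistic maps and classical
    crisp maps). Ships a 13-node case study on the health determinants of
    rural older adults and a seeded random-model generator for property
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
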