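Package: spawnhab
Title: Fuzzy-Logic Spawning-Habitat Suitability Modelling with Substrate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reach-scale spawning-habitat assessment for drifting-egg river
    fish (developed around Coreius guichenoti in a large impounded river).
    Per-cell habitat suitability is computed by Mamdani fuzzy inference over
    four factors (bed grain size, water temperature, flow velocity, water
    depth) with centroid defuzzification; bed grain size can be estimated by
    inverting an incipient-motion threshold-velocity formula; per-cell
    suitability is aggregated into weighted usable area (WUA), overall
    suitability index (OSI) and ideal/moderate/low suitability proportions.
    Includes a substrate-free three-factor baseline for model comparison and
    a calibrated synthetic reach generator for fully reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
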