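Package: croprec
Title: Within-Season Crop Recognition from Multitemporal Optical Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing corn, alfalfa and bean plots within an
    irrigation district before the crop cycle ends, from discontinuous
    cloud-free Sentinel-2 L2A acquisitions. Builds lagged multitemporal
    feature records (nine 20 m bands plus NDVI and WDVI per scene) under
    four scene-combination schemes, filters records by a WDVI vegetation
    emergence criterion, trains one-vs-one cubic-polynomial support vector
    machines and 100-tree bagged ensembles, and evaluates per-date accuracy
    with overall/producer's/user's accuracy and Cohen's kappa. Includes a
    seeded synthetic irrigation-module generator (crop phenology, soil-line
    spectral mixing, cloud calendars) so the full pipeline is testable
    without satellite downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
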