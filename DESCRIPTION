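Package: phenolidar
Title: Ground-Based LiDAR Phenotyping of Crop Biomass and Growth Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating wheat above-ground biomass and crop
    growth rate from plot-segmented LiDAR point clouds in field trials.
    Implements the 3D voxel index (3DVI), the 3D profile index (3DPI) and
    percentile-based crop height; per-genotype interpolation of trait
    series to anthesis for crop growth rate; and event-wise random-effects
    analysis giving variance components, repeatability (broad-sense
    heritability), genotype BLUPs and their correlations. Ships a
    synthetic field-trial and LiDAR-scan generator with known ground
    truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
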