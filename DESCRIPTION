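Package: borealnp
Title: Simulation of Nitrogen and Phosphorus Exports from Managed Boreal Forest Catchments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Catchment-scale simulation of nitrogen and phosphorus exports
    from boreal forests under alternative management systems (rotation
    forestry, extended rotation, continuous cover forestry, no management)
    and water-protection practices (sedimentation ponds, peak-runoff-control
    dams, wetland buffers, riparian buffer zones). Combines an empirical
    August water-table model for drained peatlands with export-coefficient
    accounting for forestry operations, logistic harvest-export response
    curves, load-dependent retention models, and a seeded synthetic
    stand-register generator, orchestrated over 50-year scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
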