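Package: autotangent
Title: Automated Six-Field Tangential IMRT Planning on Synthetic Breast Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-contained automated treatment-planning pipeline for
    hypofractionated whole-breast irradiation with six tangential IMRT fields.
    Generates synthetic left-breast voxel phantoms in three CTV size classes,
    derives planning structures (PTV margin expansion with skin crop, posterior
    ring structures), searches gantry and collimator angles by exhaustive
    beam's-eye-view field-area minimization, builds two major and four minor
    fields, optimizes fluence maps against a dose-volume objective template
    with a transparent divergent pencil-beam dose engine, runs the 105%-isodose
    hotspot re-optimization loop, and evaluates plans (DVH, homogeneity and
    conformity indices, organ-at-risk dose-volume parameters, monitor-unit
    proxy) with cohort-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    graphics,
    grDevices,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
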