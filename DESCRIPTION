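Package: microsdm
Title: Microscale Species Distribution Modelling on Gullied Hillslope Terrain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microscale habitat analysis of gullied hillslopes:
    gridding scattered elevation survey points into a fine-resolution DEM,
    deriving slope, aspect and the topographic position index (TPI),
    classifying six microtopographic landforms (valley to ridge), ordinary
    kriging of point-sampled soil and microclimate factors with
    leave-one-out validation, calibration of presence-absence logistic
    species distribution models scored by AUC, restoration-scenario overlay
    (level-trench factor replacement) with habitat-suitability
    reclassification and area accounting, and one-way ANOVA with LSD
    post-hoc letters for grouped field measurements. Includes a synthetic
    terrain and factor-field generator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    interp,
    nortest,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr,
    deldir,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
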