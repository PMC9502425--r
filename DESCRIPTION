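Package: sios2
Title: Process Parameter Prediction for Autogenic Hot Melt Extrusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predetermines twin-screw hot-melt-extrusion process parameters
    from material data and a handful of extrusion experiments, following the
    scale-independent optimization strategy (SIOS 2.0). A barrel-load model of
    the feeding section (specific feed load, powder slip) predicts the maximum
    throughput, and an autogenic (no barrel heating) viscosity correlation
    coupled to a Carreau-Arrhenius melt rheology model predicts the melt
    temperature as a function of screw speed. Includes capillary-die
    viscometry with the Weissenberg-Rabinowitsch correction, fitting routines
    for the extruder-specific correlation parameters, a virtual extruder for
    generating synthetic autogenic campaigns, and a workflow layer that plans
    experiments and produces serializable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
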