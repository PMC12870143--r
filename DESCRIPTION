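Package: tundratongue
Title: Simulation and Risk Modelling of Tongue Adhesion to Cold Metal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying "tundra tongue" injuries: a calibrated
    synthetic generator for cold-metal tongue-detachment experiments
    (block-randomized design, per-condition covariate distributions,
    mixed-effects peak detachment force with a quadratic metal-temperature
    response, and binary avulsion and cold-injury outcomes), linear
    mixed-model analysis of detachment force with nested-model comparison
    and adhesion-peak localisation, random-intercept logistic injury-risk
    models with a two-stage predicted-force risk surface, and a 2D
    transient finite-volume heat-conduction simulator for layered
    tongue-saliva-metal contact with parametric (adult and pediatric)
    geometry, perfusion via vessel temperature clamps, and isotherm,
    interface and damage-point probes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
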