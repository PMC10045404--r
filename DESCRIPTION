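Package: ecoclim
Title: Mechanistic and Correlative Species Distribution Modelling for the
    Raisin Moth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-model climatic suitability analysis for the raisin moth
    (Cadra figulilella): a CLIMEX-style mechanistic Ecoclimatic Index engine
    (weekly growth and stress indices, degree-day gating, soil-moisture bucket
    hydrology with an agricultural top-up irrigation scenario) and a
    presence-only maximum-entropy species distribution model with
    regularization-multiplier and feature-class tuning, AICc/omission-rate
    model selection, spatial-block cross-validation, jackknife variable
    importance and response curves. Includes synthetic climate and predictor
    generators with scenario transforms so the full pipeline runs offline, and
    scenario accounting (latitude-corrected suitable area, percent change,
    occurrence coverage, ensemble means).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
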