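Package: azeoblend
Title: Pseudo-Azeotrope Analysis of Binary Mosquito-Repellent Blends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterising pseudo-azeotropes in
    binary liquid repellent blends. Implements Redlich-Kister activity-model
    vapour-liquid equilibrium with location and classification of multiple
    azeotropes, open (convection-swept) evaporation simulation with
    aliquot-sampling corrections, FTIR mixing-residual and relative band
    intensity statistics, inverse composition identification by NIPALS
    partial least squares with leave-one-out model selection, Avrami-type
    composition-drift regression with residual-bootstrap confidence
    intervals for the azeotrope composition, and cup-on-arm protection
    efficacy statistics. A seeded synthetic-data generator emulating the
    oven-evaporation, thermogravimetric, spectroscopic and repellence assay
    designs makes the whole pipeline runnable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
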