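Package: vwflow
Title: Continuum Modelling of von Willebrand Factor Unfolding in Stenotic Blood Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the flow-induced unfolding of the blood
    protein von Willebrand factor (VWF) with a FENE-P configuration-tensor
    model whose relaxation time saturates with the scalar shear rate.
    Provides exact steady solutions in homogeneous shear and elongational
    flow, unfolding curves and half-unfolding thresholds, calibration of the
    unfolding parameters against a target extension curve, a steady
    axisymmetric Navier-Stokes solver for idealised stenotic arteries
    (streamfunction-vorticity form on a body-fitted grid), and a stabilised
    solver for the configuration-tensor transport equation with
    post-processing of wall extension, recirculation, and elongational-flow
    regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
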