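Package: ooablate
Title: Finite-Element Modelling of Radiofrequency Ablation of Osteoid Osteoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled electric-thermal finite-element simulation of non-cooled,
    temperature-controlled radiofrequency ablation of osteoid osteoma on 2-D
    axisymmetric geometries. Solves the quasi-static electric problem for the
    Joule heat source and the Pennes bioheat equation in enthalpy form with
    temperature-dependent tissue properties, a PI controller regulating the
    electrode r.m.s. voltage to hold a target tip temperature, and an Arrhenius
    cell-death model with perfusion shut-off. Includes a scenario factory for
    three anatomical configurations of the tumour (sclerosis-rimmed,
    trabecular-embedded, intracortical) plus an ex-vivo style validation
    layout, graded triangular mesh generation with interface-conforming
    refinement near the electrode, sensitivity and mesh-convergence studies,
    and closed-form oracles used to certify the numerics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
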