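Package: lvemsim
Title: Desk-Scale Left-Ventricle Electromechanics and Afterload Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parameterized left-ventricle geometry and tetrahedral meshing,
    rule-based myocardial fiber architecture, anisotropic monodomain
    electrophysiology with a two-variable phenomenological ionic model and
    stretch-activated mechano-electrical feedback, active-stress finite-element
    mechanics with Holzapfel-Gasser-Ogden anisotropic hyperelasticity, and a
    two-element Windkessel afterload, coupled in a staggered scheme with a
    lumped cavity-pressure surrogate for a systolic ejection simulation.
    Produces pressure-volume loops, ejection fraction, apex kinematics and
    torsion metrics on coarse desk-scale meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    methods,
    stats,
    utils,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
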