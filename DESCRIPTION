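Package: tpmsdesign
Title: Inverse Design of Anisotropic TPMS Bone Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and inverse design of bone-scaffold lattices
    built from anisotropic triply periodic minimal surfaces (TPMS). Generates
    voxel models from implicit level-set equations with independent unit-cell
    counts along the three axes, computes effective 6x6 stiffness matrices by
    voxel hexahedral finite-element homogenization, trains small feed-forward
    neural surrogates mapping structure parameters to compressive and shear
    moduli, and runs a regenerative genetic algorithm that searches the design
    space for a structure matching a target partial stiffness matrix, with
    finite-element re-verification of the selected design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lhs
Config/testthat/edition: 3
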