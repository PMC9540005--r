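Package: ossify
Title: Coupled Simulation of Bone Fracture Healing and Long-Term Remodelling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator of secondary bone fracture repair that
    couples a biphasic (poroelastic) finite-element mechanics core to
    mesenchymal stem cell diffusion, fuzzy mechano-regulated tissue
    differentiation and, after bony union, strain-energy-density and
    fatigue-damage based bone remodelling.  Idealized plated and unplated
    long-bone fracture geometries are built programmatically as labelled
    2D meshes (axisymmetric or plane strain), and the whole repair process
    is integrated over one year with adaptive time stepping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
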