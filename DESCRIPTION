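Package: cablesim
Title: Vertex-Model Simulation of Mechanical Insulation by Supracellular
    Actomyosin Cables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 2D vertex model of an epithelial placode bounded by a stiff,
    bending-resistant supracellular actomyosin cable. Builds hexagonal
    tissue meshes with tagged cable, core, interior and exterior regions;
    computes elastic, bending and active contraction forces; relaxes the
    tissue by over-damped explicit-Euler dynamics; calibrates a
    tension-free ground state by iterative cable rest-length resetting; and
    sweeps cable stiffness and bending rigidity to quantify mechanical
    insulation of the surrounding tissue from an actively constricting
    core. Also provides a companion analysis of tracked cell-vertex
    displacements toward an invagination pit, stratified by side of the
    cable, with a seeded synthetic track generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices,
    graphics,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
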