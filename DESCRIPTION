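Package: faveosim
Title: Morphoelastic Finite-Element Simulation of Epithelial Folding Through a Smooth-Muscle Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the three-dimensional mechanics of an embryonic lung
    epithelium: a closed hyperelastic shell, growing isotropically and/or
    inflated by luminal pressure, bonded to a stiffer smooth-muscle lattice
    that leaves open holes. Implements the multiplicative growth decomposition
    F = Fe Fg with a compressible neo-Hookean energy, a total-Lagrangian
    finite-element solver on first-order tetrahedra with follower pressure
    loads (Nanson's formula) and Lagrange-multiplier rigid-body constraints,
    a structured capsule/lattice mesh generator, a semi-analytic radial
    benchmark oracle, and the morphometric measurements (aspect ratio,
    epithelial thickness, per-hole protrusion amplitude) used to compare
    pressure-driven and growth-driven folding scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
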