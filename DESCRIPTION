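Package: rpmmc
Title: Monte Carlo Simulation of Primitive-Model Electrolytes with Local
    Dielectric Saturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Canonical Metropolis Monte Carlo for restricted primitive model
    (RPM) electrolytes in which the relative permittivity ramps linearly from a
    saturated contact value to the bulk solvent value over a hydration-shell
    thickness. Supports bulk (cubic, minimum-image) and slit (charged hard
    walls, charged-sheet long-range correction) geometries, single-particle and
    rigid cluster moves, and a full observable stack: species-resolved radial
    distribution functions, density-density and charge-charge correlations,
    cluster decompositions and size distributions, Yukawa tail fits of the
    screening length, a ghost-pair (modified Widom) screening-length estimator,
    phase-separation diagnostics, and double-layer density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
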