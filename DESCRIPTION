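Package: citopo
Title: Topography and Classification of Conical Intersections on Two-State Model Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds analytic two-state diabatic model Hamiltonians with a
    conical intersection of prescribed branching-space topography, locates
    minimum-energy crossing points with penalty-function and branching-plane
    projection optimizers, computes the pitch/asymmetry/tilt parameters and
    the peaked-sloped and bifurcating-single-path classification of the
    intersection, and performs structural comparisons (Kabsch superposition
    RMSD, dihedral tracking) across perturbation ensembles that emulate
    level-of-theory variation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
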