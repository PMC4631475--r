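Package: dcnrefine
Title: Deformable Complex Network Restraints for Low-Resolution
    Crystallographic Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Refinement of macromolecular crystal structures against
    low-resolution amplitude data using a deformable complex network (DCN):
    harmonic distance restraints between randomly selected atom pairs (a
    deformable elastic network, DEN) combined with harmonic restraints on
    vertex angles of randomly selected atom triplets (a deformable angular
    network, DAN), both derived from a reference structure and carrying
    equilibrium values that deform between the reference and the current
    model during refinement.  Provides simulated-annealing Cartesian
    refinement with the macrocycle/microcycle schedule, an R-free-driven
    three-dimensional grid search over the deformation parameters, and a
    synthetic-data module generating true structures, perturbed
    homology-like starting models and low-resolution diffraction amplitudes
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
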