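Package: lassofold
Title: Coarse-Grained Folding Simulation and Topology Analysis of Complex
    Lasso Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calpha-level simulation of complex lasso protein folding. The
    elastic folder model drives folding through structure-based bending and
    torsion potentials with per-angle stiffnesses, extended with
    force-shifted Lennard-Jones disulfide-bridge potentials; a Clementi-type
    Go model with 12-10 native contacts is provided for comparison. A BAOAB
    Langevin integrator propagates either model from random stretched
    configurations. Topological state along trajectories is monitored with a
    continuous lasso variable built on a reduced triangulated covalent-loop
    surface and with the Gauss linking number of open polygonal curves.
    Trajectory ensembles are classified into threading, bridge-reopening and
    open-loop folding pathways, and angular stiffnesses can be tuned by a
    stochastic Metropolis search with an evolutionary multi-force-field
    extension (population ranking plus crossover).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
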