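Package: jumpgeom
Title: Large-Deviation and Information Geometry of Markov Jump Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the large-deviation and information-geometric analysis
    of Markov jump processes on non-negative integer lattices (stochastic
    population processes and mass-action chemical reaction networks).
    Provides master-equation generators on truncated lattices, cumulant
    generating functions and exponential tilting, Legendre-dual
    large-deviation functions, Fisher metrics and Amari-Chentsov cubic
    tensors, variance-optimal importance sampling of tail probabilities with
    Chernoff bounds, Doi-Peliti Liouville (Hamiltonian) stationary-path
    dynamics with Liouville-theorem and Hamilton-Jacobi diagnostics, and the
    fully closed-form two-state linear reaction system with its conserved
    phase-space volume construction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
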