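Package: viscolbm
Title: Lattice Boltzmann Simulation of Particle Focusing in Viscoelastic
    Microchannel Flow
Version: 0.1.0
Authors@R:
    person("Mael", "Kerbiriou", email = "mael.kerbiriou@fastmail.net",
           role = c("aut", "cre"))
Description: Three-dimensional D3Q19 lattice Boltzmann (LBGK) solver for
    Oldroyd-B viscoelastic fluids in straight rectangular and circular
    microchannels, coupled to rigid-limit spherical particles built as
    stiff triangulated membranes through the immersed boundary method.
    The polymer stress is evolved with a second set of tensor
    distribution functions, walls use the non-equilibrium extrapolation
    scheme, and the package ships the analytic Poiseuille/Couette
    fixtures, dimensionless-group bookkeeping, trajectory and rotation
    analysis, and first-normal-stress-difference diagnostics used to
    study elasto-inertial particle focusing and size-based separation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
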