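Package: sphdem
Title: Hybrid Particle Simulation of Solid-Liquid Flows in 2D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified two-dimensional particle simulator in which weakly
    compressible smoothed particle hydrodynamics (SPH), coarse-grained
    bead-spring solid mechanics, and discrete element method (DEM) contact
    forces all act on one common set of computational particles. Supports
    fluid-structure interaction through Lennard-Jones no-penetration and
    ghost-value no-slip coupling, heat conduction with a latent-heat caloric
    equation of state and a solidification/melting state machine, solute
    diffusion with particle swelling and concentration-dependent adhesion,
    and a quiescent-fluid Stokes-drag mode. Ships declarative scenario
    builders for deformable-cell flows in channels and pin arrays, dispersed
    brittle solids in Poiseuille flow, casting, surface cleaning, and lava
    flow on an incline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
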