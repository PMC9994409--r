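Package: raftsim
Title: Agent-Based Simulation of Receptor Diffusion, Confinement and
    Dimerisation in Membrane Raft Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hard-disc Brownian agents on a periodic two-dimensional
    membrane patch, with circular low-diffusivity confined domains (a
    lipid-raft proxy) and stochastic monomer-dimer interconversion, built
    to study diffusion-limited dimerisation of the platelet collagen
    receptor GPVI. Includes the deterministic calculator that maps
    real-world platelet constants (volume, receptor copy number,
    single-particle-tracking diffusivity, raft geometry) to simulation
    units, the tick-level simulation engine with excluded volume,
    replicate management and equilibrium averaging, ten preset parameter
    sweeps over diffusivity contrast, confined-domain area, molecular
    crowding and reaction rates, and regression-based estimation of the
    confined membrane area fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
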