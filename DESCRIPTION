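Package: crowdLBM
Title: Crowding-Corrected Lattice Boltzmann Simulation of Molecular
    Diffusion in Two Dimensions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mesoscopic simulation of diffusion of hard-disk and
    lattice-square molecules in crowded two-dimensional media, such as
    lateral diffusion of proteins in cell membranes. Implements a D2Q5
    BGK Lattice-Boltzmann diffusion engine together with a crowding
    correction in which post-collision populations are scaled by the
    Scaled Particle Theory probability of finding free space in the
    target voxel, an on-lattice variable-time-step kinetic Monte Carlo
    reference simulator with excluded volume (compiled inner loop), and
    the comparison metrics (relative distribution error, tracer mean
    squared displacement) used to validate the mesoscopic engine against
    the particle-level reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
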