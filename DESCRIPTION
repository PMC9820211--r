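Package: thzchannel
Title: Ion-Permeation Analysis of Potassium-Channel Trajectories Under
    Terahertz Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-file ion permeation through a
    KcsA-like potassium-channel selectivity filter driven by a midinfrared
    (terahertz) oscillating electric field.  Provides trajectory and
    site-map data structures with columnar and PDB readers/writers, a
    reduced-scale overdamped Langevin channel simulator (multi-well
    binding landscape, membrane-voltage tilt, oscillating field, screened
    ion-ion Coulomb repulsion, resonant carbonyl-oscillator coupling to
    the S1 barrier), selectivity-filter occupancy-state censuses,
    permeation-event detection with flux and current estimation, soft-
    versus direct-knock-on mechanism classification, potential of mean
    force by Boltzmann inversion, carbonyl IR absorption spectra from
    dipole time series, and pore-radius profiling from symmetric carbonyl
    oxygen pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    pracma,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
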