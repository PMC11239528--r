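Package: smfret
Title: Photophysical Simulation and Triplet-State Correction of
    Single-Molecule FRET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact steady-state calculators and a photon-level Gillespie
    simulator for the joint photophysical dynamics of a FRET donor-acceptor
    fluorophore pair, including singlet ground/excited and triplet states
    (three-, four- and nine-state continuous-time Markov models).  Implements
    the complete single-molecule FRET correction pipeline (spectral crosstalk,
    acceptor direct excitation, gamma and the triplet/saturation zeta
    correction), fluorescence correlation spectroscopy model fitting with
    antibunching, triplet blinking and diffusion terms, and confocal-style
    photon-burst selection with per-burst FRET efficiencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
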