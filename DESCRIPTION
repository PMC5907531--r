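Package: hergmarkov
Title: Markov-Chain Gating Models of hERG1 Channel Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and fitting of Markov-chain gating schemes for the
    hERG1 (Kv11.1) potassium channel isoforms hERG1a and hERG1b. Builds the
    5-state linear (M-model 1) and looped (M-model 2) gating schemes with
    voltage-dependent Eyring-form transition rates, simulates standard
    voltage-clamp protocols (steady-state activation, envelope of tails,
    deactivation, recovery from inactivation) by exact matrix-exponential
    propagation of the master equation, extracts the derived measurements
    (Boltzmann activation curves, exponential deactivation time constants),
    and globally fits multiplicative rate-correction factors to
    multi-protocol data with seeded multi-start optimization. Fitted
    kinetics can be propagated into a paced ventricular cell model, a
    165-cell transmural fiber, and a pseudo-ECG to compare action-potential
    duration and QT interval across isoform mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
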