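Package: msmex
Title: Markov State Model Analysis of Peptide-MHC Class II Conformational
    Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify rare, exchange-competent conformations of
    peptide-loaded MHC class II complexes from molecular dynamics
    trajectory ensembles.  Implements the full analysis chain: pairwise
    C-alpha distance featurization, time-lagged independent component
    analysis (TICA), k-means discretization shared across simulation
    conditions, reversible maximum-likelihood Markov state model
    estimation with implied-timescale and Chapman-Kolmogorov validation,
    PCCA+ metastable coarse-graining, trajectory-level bootstrap
    confidence intervals for populations, free energies and coarse
    rates, bootstrapped pairwise interaction frequencies with
    significance calls, per-state structural observables (side-chain
    flip probability, contact and solvent-contact frequencies, helicity
    profiles), NMR-detected hydrogen/deuterium exchange quantitation in
    the EX2 limit (decay fitting, half-life classification, protection
    factors, opening free energies, chemical shift perturbation), and a
    harmonic center-of-mass/inertia-tensor simulation restraint with
    analytic gradients and a periodic-image distance monitor.  A
    synthetic-data generator with a hidden metastable Markov chain and
    known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
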