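Package: dyadsync
Title: Interbrain Phase Synchronization Analysis for EEG Hyperscanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of dual-EEG (hyperscanning) recordings from
    speaker-listener dyads. Provides zero-phase FIR band filtering and
    Hilbert-transform phase extraction, single-trial phase-locking values
    (PLV) across all interbrain electrode pairs, speech amplitude-envelope
    entrainment with intra-brain correction, trial-shuffled role-preserving
    surrogate nulls, nonparametric bootstrap paired tests with
    Benjamini-Hochberg false discovery rate control, and regression-based
    mediation analysis that separates interbrain coupling explained by the
    shared speech signal from coupling that is not. A synthetic dyad
    generator with controllable phase coupling and envelope entrainment
    supports validation of every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: fftw3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
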