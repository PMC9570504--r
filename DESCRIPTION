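Package: gjvolt
Title: Transjunctional Voltage Gating and Single-Channel Analysis of Gap
    Junction Currents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of dual whole-cell voltage-clamp
    recordings from gap-junction-coupled cell pairs: a stochastic Markov
    simulator of junctional currents whose stationary behaviour follows a
    two-state Boltzmann voltage-gating law, reduction of macroscopic
    current traces to normalized steady-state conductance with bounded
    multistart Boltzmann fitting, single-channel analysis (Gaussian
    low-pass filtering, all-point amplitude histograms with
    sum-of-Gaussians level fitting, slope unitary conductance regression,
    half-amplitude threshold idealization and open dwell-time statistics),
    self-contained rank-based group statistics (Kruskal-Wallis, Dunn post
    hoc, Mann-Whitney, Student's t), and a van der Waals steric clash
    scanner for connexin amino-terminal/TM2 interfaces in PDB coordinate
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
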