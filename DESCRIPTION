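Package: chromotrace
Title: Chromatin Locus Trajectory Analysis: Dynamics, Compaction, Tethering
    and Nuclear Radiality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for live-cell single-particle tracking of
    genomic loci on a single chromosome. Computes time- and
    ensemble-averaged mean square displacements with power-law
    (anomalous-diffusion) fits, short-time effective diffusion constants,
    gyration (trajectory) radii, effective spring constants from step-size
    regression under an overdamped Langevin model, Rouse polymer tethering
    inversion (chain stiffness, tether spring constant), chromosome
    compaction exponents from locus-pair distances, cell-to-cell versus
    temporal variation decomposition, and normalized nuclear radial
    distance statistics. Ships tethered-bead (Ornstein-Uhlenbeck), Rouse
    chain and fractional Brownian motion simulators that generate
    synthetic trajectories with the statistical structure the estimators
    assume, so every stage is verifiable against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
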