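Package: megfc
Title: Source-Space MEG Functional Connectivity with Beamformers and
    Simulation-Based Nulls
Version: 0.1.0
Authors@R: person("megfc", "developers", email = "megfc@example.org",
    role = c("aut", "cre"))
Description: Tools to measure functional connectivity between brain
    regions from magnetoencephalography (MEG) sensor data projected into
    source space with a scalar linearly-constrained minimum-variance
    (LCMV) beamformer. Implements spherical-conductor dipole lead
    fields, covariance estimation with regularized weights and
    orientation optimization, band-limited Hilbert-envelope and
    coherence connectivity metrics (AEC, CAE, Coh, ICoh), signal-leakage
    diagnostics based on weights and lead-field correlation, a
    simulated-dipole null framework with binned leakage correction,
    percentile and exact Wilcoxon signed-rank significance, volumetric
    map comparison utilities, and a synthetic-data generator so every
    analysis is testable without recordings. Volumetric maps are read
    and written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
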