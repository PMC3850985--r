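Package: radialpwv
Title: Self-Gated Radial Phase-Contrast MRI and Local Pulse-Wave Velocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospectively self-gated radial phase-contrast cine
    MRI of small pulsating vessels and for local pulse-wave velocity (PWV)
    estimation with the flow-area (QA) method. Implements the modified
    golden-angle projection ordering with heartbeat-interleaved sublists,
    asymmetric (partial-echo) radial trajectories with gradient-delay
    modelling, navigator extraction from the k-space centre with Butterworth
    low-pass and Gaussian high-pass filtering, trigger detection and
    respiratory gating, Kaiser-Bessel gridding with Pipe's iterative density
    compensation, two-echo B0 field mapping with 2-D phase unwrapping,
    time-segmented conjugate-phase off-resonance correction, per-pixel
    velocity mapping, automated vessel segmentation, and linear fitting of
    the early-systolic Q(A) relation. A dynamic pulsating-vessel digital
    phantom with a full MR forward model (cardiac variability, respiration,
    inflow enhancement, off-resonance, gradient delays, noise) provides
    ground truth so the whole chain is testable without a scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    EBImage,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
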