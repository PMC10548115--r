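Package: psoctrack
Title: Doppler-Tracked Polarization-Sensitive OCT Needle Guidance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and processing toolkit for forward-viewing
    fiber-in-needle polarization-sensitive optical coherence tomography
    (PS-OCT) probes. Provides a fringe-level swept-source simulator of a
    needle probe traversing layered birefringent tissue phantoms with an
    exact Jones-matrix oracle, spectrally binned tomogram reconstruction
    with Stokes-vector polarimetry (intensity, cumulative phase
    retardation, optic-axis orientation), Doppler phase-shift odometry of
    the needle tip (jitter gating, causal sliding-median filtering,
    tip-reference drift correction, depth averaging), and the remapping of
    needle-referenced M-mode data into surface-referenced visualizations
    with a frozen traversed-tissue record.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
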