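Package: hdmead
Title: Adaptive Template-Based Denoising for High-Density Microelectrode
    Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and adaptive, feature-template-based denoising of
    large-scale extracellular recordings from high-density CMOS
    microelectrode arrays (HD-MEAs). Provides band-limited filtering, hard
    threshold local field potential (LFP) event detection and precise
    timing spike detection (PTSD), a network-derived feature template for
    separating genuine LFP/spike events from electrical, mechanical and
    environmental noise (50 Hz line pickup, perfusion transients,
    inductive coupling, spurious spike trains, chip calibration faults),
    classical denoising baselines (FIR, Savitzky-Golay, wavelet, Fourier),
    SNR and RMS benchmarking, binned spatiotemporal activity maps with
    center-of-activity trajectories, PCA plus mean-shift waveform
    clustering with silhouette assessment, and a seeded ground-truth
    simulator of HD-MEA recordings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
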