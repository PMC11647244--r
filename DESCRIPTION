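Package: wavelattice
Title: Lattice Neural Field Simulation with Wave-Interference Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reductionistic neuronal field model: a two-dimensional
    lattice of coupled virtual oscillators (cortical-column analogues) evolving
    by a twice-integrated grid Laplacian with tunable lateral coupling and
    damping. Provides the exact normal-mode (damped-wave) solution of the
    model on periodic grids, a wave-interference encoder/decoder for static
    images, time-varying stimuli and audio, virtual electrodes at unit, LFP
    and EEG scales, and a signal-analysis suite (spectral peak statistics,
    short-time Fourier transforms, magnitude-squared coherence, wave-speed
    measurement, thresholded correlation networks, Lempel-Ziv complexity, and
    induced/evoked high-frequency power analysis of grating-stimulation
    sessions). Named parameter presets reproduce simulated physiological and
    pathological activity states (waking, slow-wave sleep, anesthesia,
    lesioned, jittered-coupling, and seizure regimes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
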