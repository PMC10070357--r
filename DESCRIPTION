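Package: mfdburst
Title: Single-Molecule FRET Burst Analysis with Multiparameter Detection
    and Pulsed Interleaved Excitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Burst-wise analysis of diffusion-based single-molecule FRET
    experiments recorded with multiparameter fluorescence detection (MFD)
    and pulsed interleaved excitation (PIE). Provides a photon-stream data
    model with PIE time gating, sliding-window burst search, corrected FRET
    efficiency and stoichiometry with crosstalk/direct-excitation/detection
    corrections, burst-wise fluorescence lifetimes by maximum likelihood,
    steady-state and time-resolved anisotropies with a wobbling-in-a-cone
    geometry, dynamics indicators (static FRET line with lifetime-shift
    significance testing, FRET-2CDE with a photon re-coloring null, burst
    variance analysis), species-filtered fluorescence correlation
    spectroscopy, and dynamic photon distribution analysis for two-state
    exchange with static sub-states. A forward Monte-Carlo generator of
    photon streams (Brownian transits of a 3D Gaussian spot, Markovian
    conformational kinetics, two-color emission with lifetimes,
    polarization, crosstalk and background) makes every stage testable
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
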