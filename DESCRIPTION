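Package: hopfbundle
Title: Feedback-Controlled Hopf Oscillator Model of Hair-Bundle Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a Stuart-Landau (Hopf normal form)
    model of active hair-bundle mechanics with two feedback pathways: an intrinsic
    self-tuning law that poises the bundle near its Hopf bifurcation, and efferent
    input represented as parametric forcing that supplants the self-tuned control
    parameter while active. Provides piecewise forcing protocols, deterministic
    segment-wise integration with a compiled right-hand side, closed-form amplitude,
    frequency and response laws, trace statistics (instantaneous amplitude and phase,
    vector strength, phase-locked amplitude, Bartlett power spectra, response widths,
    recovery times), and drivers for the standard simulation studies (recovery after
    overstimulation, parametric modulation of spontaneous oscillation, Arnold tongues,
    power-ratio and tuning-width scans, efferent rescue of quiescence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
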