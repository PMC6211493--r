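Package: erdlia
Title: Online Event-Related Desynchronization Estimation by Lock-In
    Demodulation and Sliding FFT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for low-latency estimation of sensorimotor
    event-related desynchronization (ERD) from multichannel EEG. Implements
    two causal estimators of alpha-band power at a participant-specific
    frequency of interest: a conventional sliding-window FFT power spectral
    density pipeline and a lock-in-amplifier (quadrature demodulation)
    pipeline, both feeding the standard ERD transform against a rest-phase
    baseline. Includes a large-Laplacian spatial filter, EDF/CSV recording
    I/O, ERD-threshold trigger simulation emulating brain-state-dependent
    TMS sessions, motor-evoked-potential (MEP) analysis of surface EMG
    epochs, seeded synthetic EEG/EMG generators with ground-truth envelopes,
    and a benchmark harness comparing detection delay, accuracy and
    stability of the two estimators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
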