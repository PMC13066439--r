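Package: inharmmn
Title: Inharmonicity and Auditory Mismatch Responses: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the inharmonicity of complex tones shapes
    auditory mismatch responses. Synthesizes harmonic and frequency-jittered
    complex tones (geometric jitter schedule, 30 Hz spacing rejection sampling,
    Butterworth high-pass filtering, half-Hanning ramps, BS.1770-style loudness
    normalization), builds roving-oddball stimulus sequences with
    deviant/standard/excluded labeling, simulates 3-up-1-down adaptive
    staircases, generates synthetic ERP peak tables and epochs, extracts
    MMN/P3a peak measures from difference waves, fits sigmoid and polynomial
    mixed-effects models of amplitude versus the differential entropy of the
    jitter distribution, and runs simulation-based power analyses for
    repeated-measures designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nlme,
    signal,
    stats,
    utils
Suggests:
    car,
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
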