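Package: cardiocuff
Title: Simulation and Analysis of Multi-Site Pressure-Stimulation
    Cardiovascular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing multi-channel cardiovascular
    recordings acquired under a seven-phase cuff pressure-stimulation protocol.
    Provides a seeded 27-channel signal simulator (ECG, heart and lung sounds,
    photoplethysmographic and pressure pulses, dual-wavelength blood-oxygen
    signals, six cuff-pressure traces), instrument calibration formulas (ECG
    voltage, SpO2 ratio-of-ratios parabola, linear pressure fits), cardiac
    cycle selection by the base-time rule, per-cycle time-domain parameters,
    oscillometric blood pressure, pulse wave velocity, occlusion-phase
    blood-oxygen trend statistics, and FFT harmonic-band statistics, all as
    tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
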