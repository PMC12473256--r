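Package: pulsema
Title: Motion-Artifact Modelling for Arterial Pulse Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how motion artifacts distort arterial pulse signals
    measured by accelerometers and photoplethysmography (PPG) sensors. The
    tissue-contact-sensor stack between the artery and the sensor is modelled
    as a one- or two-degree-of-freedom mass-spring-damper system whose
    parameters drift with low-frequency baseline motion (time-varying system
    parameters, TVSPs). The package synthesizes multi-harmonic pulse waveforms
    and band-limited baseline drifts, integrates the time-varying equations of
    motion, separates additive (drift) from multiplicative (TVSP) distortion,
    computes equivalent-force representations of the artifact, and quantifies
    the distortion through spectra, per-cycle heart rate, cubic-spline baseline
    estimation, and harmonic-sideband energy reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
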