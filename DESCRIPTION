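Package: shutterlum
Title: Time-Gated Luminescence Analysis from Rolling-Shutter Camera Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulation and inverse analysis of time-gated
    luminescence measurements made with a rolling-shutter CMOS camera
    observing scenes under pulsed (PWM) LED excitation. Because sensor rows
    expose sequentially, a strobe that is fast relative to the frame
    traversal produces horizontal banding; emitters with microsecond- to
    millisecond-range lifetimes decay visibly across the "off" bands. The
    package renders physically faithful noisy captures of such scenes
    (closed-form periodic-steady-state emission kinetics, Poisson shot
    noise, Gaussian read noise, quantisation), and recovers strobe
    frequency, duty cycle, emissive lifetimes, and species identity from
    banded images. It also fits and inverts Stern-Volmer oxygen/pressure
    quenching and thermal-quenching temperature calibrations, and ships
    scene generators emulating co-deposited fast/slow emitters,
    homogeneous dye mixtures, multi-ink security tags, and
    pressure/temperature response series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
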