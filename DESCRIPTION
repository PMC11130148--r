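Package: sonoretina
Title: Acoustic Holography and Imaging-Guided Stimulation Toolkit for an
    Ultrasound Retinal Prosthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computational core of an ultrasound retinal prosthesis built
    around a 16x16 phased array: band-limited angular-spectrum propagation of
    scalar pressure fields with a direct Rayleigh-Sommerfeld oracle, holographic
    decoding of arbitrary target patterns into per-element amplitude/phase
    drives, B-mode eye-phantom synthesis with Canny-edge auto-alignment (retina
    depth and array tilt), beam metrics (FWHM, steering coverage, Snellen acuity
    conversion, SSIM, layered-eye distortion), exposure dosimetry (MI, ISPPA,
    ISPTA, TI, acoustic radiation force, frequency-threshold fits), and a
    multi-unit-activity response-mapping pipeline with modified-Akima
    interpolated activation maps, exercised end to end on synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    png,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
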