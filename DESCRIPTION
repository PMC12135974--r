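Package: xtalspec
Title: Correction and Kinetic Analysis of Single-Crystal Optical
    Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing UV-Vis absorption spectra recorded on
    single macromolecular crystals with fibre microspectrophotometers.
    Computes absorbance from raw sample/reference/background detector
    traces, models and subtracts the non-absorbing background (Fresnel
    reflectivity with Cauchy dispersion plus Rayleigh scattering, or
    power-law fallbacks) by segment-weighted nonlinear least squares,
    smooths spectra (Savitzky-Golay, rolling mean), detects and removes
    nanosecond-laser dents, scores per-wavelength confidence from photon
    counts, extracts band time traces with mono-exponential and Hill
    kinetic fits, and decomposes time-resolved difference-spectrum series
    by singular value decomposition. Includes a synthetic-data generator
    emulating the optical artefacts the corrections address, and a
    config-driven processing pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
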