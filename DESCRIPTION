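Package: zerocross
Title: Zero-Crossing Derivative Spectrophotometry for Two-Component Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous quantitation of two analytes with heavily
    overlapping UV absorption spectra by zero-crossing derivative
    spectrophotometry.  Provides spectrum containers and CSV/JCAMP-DX
    readers, Beer-Lambert simulation of two-component mixtures with
    Gaussian band models and instrument noise, instrument-style
    difference derivatives (orders 1-4, configurable delta-lambda) with a
    Savitzky-Golay alternative, zero-crossing detection and working
    wavelength selection, calibration-curve fitting and inversion, and a
    full assay validation battery (within/between-day accuracy and
    precision, standard-addition recovery, two-sample t and variance
    ratio F method comparison).  A single driver runs the complete
    in-silico study from simulated spectra to machine-readable report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, signal, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
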