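Package: mechanomr
Title: Hydrogel-Sensor MR Stress Quantification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies local mechanical stress from T2*-weighted MR volumes
    containing hydrogel micro-sensor dark spots. Detects single-particle
    spots, computes the reciprocal-intensity signal-to-background ratio,
    inverts an empirical biexponential stress-signal calibration by
    Newton-Raphson, links particles across longitudinal imaging sessions to
    obtain stress-loading-rate statistics, registers MR-frame sensor
    coordinates to fluorescence volumes by coherent point drift, and
    summarises stress by fluorescence-defined tissue region. Includes an
    analytic compressible Neo-Hookean surrogate for the compression-device
    mechanics and a synthetic-data module that emulates calibration phantoms,
    growing tumor time series and paired-modality registration scenes with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
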