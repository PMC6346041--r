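Package: optomap
Title: Multiparametric Cardiac Optical Mapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-channel (transmembrane voltage and intracellular
    calcium) fluorescence movies from cardiac optical mapping experiments.
    Provides per-pixel signal conditioning (spatial and zero-phase temporal
    smoothing, drift removal, amplitude normalization, SNR masking), beat
    segmentation and waveform kinetics (activation time, 20-90% rise time,
    action potential and calcium transient duration at a repolarization level,
    exponential calcium decay rate), activation and phase maps, Bayly-style
    polynomial-surface conduction velocity estimation with longitudinal and
    transverse sector summaries, and a seeded synthetic generator of paced,
    anisotropically propagating waves with exact per-pixel ground truth for
    validation. Movies interchange as multipage 16-bit TIFF or raw binary with
    a JSON calibration sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tiff,
    png,
    signal,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
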