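Package: aiagate
Title: Calcium Response Detection and AND-Gate Biophysics for C. elegans
    Chemosensory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies single-trial GCaMP fluorescence responses of
    C. elegans chemosensory and interneuron recordings: delta-F/F0
    normalization against a median pre-stimulus baseline, five-frame
    smoothing, dual-threshold (magnitude plus derivative) calling of
    activation and inhibition onsets, cumulative response-time profiles
    with two-sample Kolmogorov-Smirnov comparison, bootstrap estimation of
    inter-neuron response lags, response magnitudes and rise times, and
    linear photobleaching correction. Ships a synthetic trace generator
    with ground truth for validation, and a conductance-based simulator of
    a bistable interneuron membrane whose depolarized plateau is reached
    only under coincident gap-junction drive and release from chloride
    shunting (AND-gate logic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
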