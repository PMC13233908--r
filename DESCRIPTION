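Package: pscbench
Title: Simulation and Benchmarking of Spontaneous Postsynaptic Current Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating automated detection of spontaneous excitatory
    and inhibitory postsynaptic currents (sEPSC/sIPSC) in voltage-clamp
    recordings. Simulates gap-free current traces with known ground-truth
    events and a configurable noise/artifact library; implements three
    classical detector families (baseline-threshold, template matching with
    correlation or Clements-Bekkers scoring, and robust median/MAD
    thresholding on Butterworth-filtered traces) plus a small trainable 1-D
    convolutional network detector; and scores any detector against a
    reference annotation with tolerance-window one-to-one event matching,
    precision, recall, F-beta (beta = 0.3) overall and stratified by event
    amplitude, together with physiology summaries (frequency, amplitude,
    inter-event intervals, ECDFs, two-sample Kolmogorov-Smirnov tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    withr,
    pROC,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse
Config/testthat/edition: 3
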