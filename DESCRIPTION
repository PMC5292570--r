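Package: myobench
Title: Synthetic Surface EMG Instrumentation Bench and Myoelectric
    Pattern-Recognition Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-channel surface electromyography (sEMG)
    measurement end to end: band-limited stochastic muscle sources
    amplitude-modulated per motion class, electrode transfer differences
    between gelled Ag/AgCl and dry conductive-polymer electrodes, source
    impedance imbalance and its conversion of common-mode mains and meter
    interference into differential noise, amplification, band-pass and
    notch filtering, rail saturation, and saturated-segment exclusion.
    On top of the simulator it implements a myoelectric pattern-recognition
    pipeline (sliding 128 ms epochs, smoothed FFT power features at eight
    fixed frequencies per channel, a 24-32-5 feed-forward neural network
    trained by backpropagation) and the evaluation analyses: sliding RMS
    envelopes, Pearson correlation between electrode views, band-power
    comparison, rest-state noise-level classification, and mean/SD
    summaries of packaged reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
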