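Package: nsinet
Title: Mixed Spiking/Non-Spiking Neural Networks with Sub-Threshold Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mixed neural networks that couple a sub-threshold
    (non-spiking) interneuron into a spiking central-pattern-generator network
    of adaptive exponential integrate-and-fire neurons. The non-spiking
    interneuron translates an analog input current into graded current
    injections and voltage-characteristic manipulations of post-synaptic
    spiking neurons, shaping the amplitude, frequency and phase of the
    rate-coded motor output. Provides a clock-driven network engine, an
    event-driven counterpart with asynchronous membrane-potential
    reconstruction, Ben's Spiker Algorithm for analog-to-spike encoding,
    a closed-loop amplitude-regulation demonstration, and analysis tools for
    burst peaks, frequency and phase.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
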