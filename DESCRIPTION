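Package: envwhiten
Title: Temporal Whitening Analysis of Envelope Coding in Electrosensory
    Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how sensory neurons
    encode second-order stimulus features (envelopes) and whether their
    tuning temporally whitens naturalistic input.  The package generates
    band-limited amplitude-modulated noise carriers with sinusoidal or
    power-law ("naturalistic") envelopes, simulates envelope-tuned spiking
    neurons as inhomogeneous Poisson processes and envelope-tracking
    electric-organ-discharge (EOD) behavior, and provides the full analysis
    chain: spike detection, cycle histograms with sinewave fits, neural and
    behavioral gain estimation, power-law tuning-curve fits, response-power
    prediction under natural stimulus statistics, the whitening index,
    spike-triggered averages, and paired/unpaired nonparametric population
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
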