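Package: nadhlife
Title: Simulation and Analysis of NADH Time-Resolved Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-correlated single photon counting (TCSPC) analysis
    of NADH autofluorescence: simulation of Poisson-sampled decay histograms and
    polarised channel triplets under pulsed excitation, instrument-response
    reconvolution fitting of multi-exponential decay models with incomplete-decay
    (periodic wrap) correction, steady-state and time-resolved fluorescence
    anisotropy analysis, constrained free/bound two-species decomposition against
    an enzyme-binding model, and series-level microenvironmental trend analysis
    (temperature, pH, protein titration).
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
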