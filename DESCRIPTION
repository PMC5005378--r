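Package: circsleep
Title: Sleep and Circadian Analysis of Rodent EEG Under Shortened Light-Dark Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mouse EEG/EMG recordings under shortened
    light-dark cycles: rule-based vigilance-state scoring on 4-s epochs,
    state-specific power spectra, theta-gamma phase-amplitude coupling with
    surrogate z-normalization and cluster-based permutation statistics,
    chi-square periodogram and cosinor rhythm analysis (individual and
    population-mean), and two-process-model sleep homeostasis fits (exponential
    slow-wave-activity decay and logistic buildup). Includes a synthetic-data
    generator with known ground truth that embodies the statistical structure
    the analyses assume, and an orchestrating pipeline with a reproducible
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
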