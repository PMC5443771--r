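Package: septfc
Title: Time-Frequency Component Analysis of Somatosensory Evoked Potentials
    for Spinal Injury-Level Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes averaged somatosensory evoked potential (SEP)
    recordings into Gabor time-frequency components by greedy matching
    pursuit, categorizes components by relative energy (high / middle / low),
    characterizes their joint time-frequency distributions with kernel
    density estimation and local-peak detection, and classifies recordings
    with a three-stage cascade of radial-basis-function support vector
    machines (normal vs injured, then C5 vs C4/C6, then C4 vs C6) under a
    ten-times-repeated ten-fold cross-validation protocol with log2 grid
    search. Includes a calibrated synthetic-SEP generator so the whole
    pipeline is testable without animal recordings, plus delimited-text and
    EDF readers for real traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse
Config/testthat/edition: 3
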