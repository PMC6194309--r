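Package: neurogram
Title: Template-Matching Decoding of Speech Tokens from Neural Population
    Spike Trains
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding vowel-consonant-vowel speech tokens from
    population spike-train recordings. Implements a time-shifted
    nearest-neighbour classifier over smoothed peri-stimulus time histogram
    matrices (neurograms) with token, phoneme and hierarchical modes and
    leave-one-repetition-out cross-validation; lifetime and population
    sparseness; d-prime and discrimination-specificity statistics derived
    from confusion matrices; characteristic-frequency neighbourhood PSTH
    correlations; smoothing-window and population-size sweep experiments;
    robust-threshold spike detection from raw extracellular traces; and a
    seeded inhomogeneous-Poisson population simulator emulating dense
    auditory-nerve-like through sparse cortex-like codes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
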