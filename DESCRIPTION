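Package: alphastates
Title: Bistable Alpha-State Dynamics of EEG During Neurofeedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of the bistable dynamics of the EEG alpha rhythm
    (8-13 Hz) during closed-loop alpha neurofeedback training. Epoch-wise
    alpha band power is reduced to a binary high/low alpha state sequence by
    individualized thresholding, from which fractional occupancy, dwell-time
    distribution statistics and two-state Markov transition probabilities
    are estimated and correlated with changes in cold-pressor pain ratings.
    Includes a synthetic bistable-EEG cohort generator with known ground
    truth, an offline re-implementation of the real-time band-power
    feedback dial, and an end-to-end pipeline producing tidy per-participant
    by session by threshold parameter tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
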