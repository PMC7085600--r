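Package: throwrec
Title: Upper-Extremity Throwing-Action Recognition from Wearable Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recognizes the six phases of an overhand throw (wind-up, stride,
    arm cocking, arm acceleration, arm deceleration, follow-through) from two
    synchronized tri-axial accelerometer channels worn on the forearm and upper
    arm. Raw 16-bit counts are smoothed with a scalar Kalman filter, normalized
    to the full-scale range, leveled into ternary triples with a symmetric
    +/-0.35 band, encoded into a 27-symbol alphabet per channel, and matched
    phase-by-phase against a template database with the longest-common-
    subsequence algorithm. Includes a readiness gate, error-message
    classification for common throwing faults, identification-rate aggregation,
    a synthetic two-channel signal generator with ground-truth labels, CSV/JSON
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
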