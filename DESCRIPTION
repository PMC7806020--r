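Package: predbot
Title: Markov-Chain Robotic Predator Control and Zebrafish Avoidance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-silico studies of closed-loop animal-robot
    interaction experiments in which a robotic predator replica stimulates a
    single zebrafish in a binary-choice tank. Implements the finite-state
    Markov-chain behavior policy of the replica (calibration from scored
    sequences, stationary analysis, marginalization from a six-state
    closed-loop chain to a three-state open-loop chain), a virtual-arena
    simulator that stands in for the physical platform and the live fish,
    the behavioral-metrics pipeline (avoidance, geotaxis, and activity
    measures on smoothed 30 Hz trajectories), and a discrete plug-in
    transfer-entropy estimator with a surrogate-pairing permutation test for
    detecting directed robot-to-fish coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
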