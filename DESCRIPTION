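Package: alphashare
Title: Cross-Task Decoding of Oscillatory EEG Representations Shared
    Between Visual Imagery and Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether visual mental imagery and visual
    perception recruit common object representations in band-limited EEG
    oscillations. Implements Morlet time-frequency decomposition of epoched
    EEG into induced power, pseudo-trial averaging, pairwise linear-SVM
    time-generalization decoding across tasks (with electrode-subset,
    individual-alpha, alpha-power-split and broadband variants), conversion
    of classifier weights into activation patterns for sensor-space
    localization, representational similarity analysis against visual,
    semantic-category and auditory model dissimilarity matrices, and
    group-level sign-permutation statistics with cluster-size inference.
    Ships a synthetic-EEG generator with known ground truth (object-specific
    induced alpha bursts over posterior channels in 1/f noise) so the whole
    pipeline is testable end to end without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    rhdf5,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
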