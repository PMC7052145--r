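Package: crqsync
Title: Cross-Recurrence Quantification of Group Cardiac Synchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying cardiac synchrony among small groups of
    spectators from beat-to-beat (RR) interval data. Tachograms are resampled
    to evenly spaced RR series by cubic-spline interpolation, delay-embedded
    with the embedding dimension chosen by false nearest neighbours, and
    compared pairwise through cross-recurrence plots. Four recurrence metrics
    (recurrence rate, diagonal line entropy, laminarity, longest diagonal)
    summarise each pair; per-participant in-group and out-group synchrony is
    the mean over three pairings, and synchrony is related to the convergence
    of Likert ratings within a group via Bonferroni-corrected Pearson
    correlations. A seeded generator of quartet-structured sessions with a
    shared low-frequency driver makes every stage testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
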