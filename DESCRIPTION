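Package: imagfear
Title: Fear Conditioning and Mental Imagery Decoding Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-visit differential fear conditioning
    experiments in which conditioned stimuli are viewed, imagined, or regulated
    by mental imagery. Implements trial-schedule construction with
    reinforcement and analysis-inclusion rules, skin conductance response
    preprocessing and trough-to-peak trial scoring, region-of-interest
    multivariate cross-classification (linear support vector machines trained
    on viewed stimuli and tested on imagined or regulated trials), group-level
    permutation and bootstrap inference for decoding accuracies, and
    repeated-measures behavioural statistics with generalized eta-squared.
    A synthetic-data generator with known ground truth supports end-to-end
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
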