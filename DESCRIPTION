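Package: sees
Title: Consensus Modelling for Subjective Evidence Evaluation Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for administering and analysing the Subjective Evidence
    Evaluation Survey (SEES), an 18-item instrument with which analysis teams
    in many-analysts studies rate the subjective evidence for a hypothesis and
    the methodological appropriateness of the study. Provides the packaged
    instrument schema, response recoding and validation, a hierarchical
    Bayesian cultural-consensus (latent truth rater) model for ordinal
    responses with per-team scepticism and per-item difficulty, a synthetic
    response generator with parameter-recovery experiments, belief-updating
    descriptives, Bayesian Pearson and rank-based Spearman correlation tests
    with directional Bayes factors, and the Delphi item-screening rule used
    during instrument development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
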