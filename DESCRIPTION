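Package: pseudoIPD
Title: Pseudo Individual Participant Data Meta-Analysis of Baseline and
    Follow-Up Continuous Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs individual-level (pseudo IPD) baseline and
    follow-up records from per-arm aggregate statistics (means, standard
    deviations and the baseline-follow-up correlation) so that
    likelihood-based ANCOVA linear mixed models fitted to the pseudo data
    reproduce exactly the analysis of the unobserved true individual
    participant data. Provides the surrounding one-stage and two-stage
    ANCOVA model family (stratified-study and random-study models, with
    optional treatment-by-baseline interaction and four within-study
    residual variance structures, fitted by REML), correlation recovery
    from change-score standard deviations or the standard error of the
    difference in mean change, standard aggregate-data comparators
    (change-score, final-value and baseline meta-analyses,
    meta-regression), between-within and Satterthwaite confidence
    intervals, and a simulation module for validating the
    sufficient-statistic equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    metafor,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
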