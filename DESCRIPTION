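Package: survrules
Title: Survival Rule Induction with Log-Rank Rule Quality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Induces sets of interpretable survival rules from right-censored
    data with a separate-and-conquer covering algorithm. Candidate conditions
    are scored by the two-sample log-rank statistic between observations
    covered and not covered by the rule; each rule concludes with a
    Kaplan-Meier estimate of the survival function of its covered
    observations. Predictions average the curves of all covering rules, with
    a whole-sample default curve for uncovered observations. Includes
    censoring-weighted Brier score and integrated Brier score evaluation with
    censoring-stratified cross-validation, rule significance assessment with
    false-discovery-rate control, a synthetic right-censored data generator
    with known region-structured hazards, CSV/ARFF readers, a plain-text
    model format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    foreign,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
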