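Package: condobs
Title: Self-Consistent Bayesian Observer Models of Post-Decision Orientation Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation, fitting, and comparison of self-consistent Bayesian
    observer models for orientation judgment tasks in which subjects first
    categorize a stimulus as clockwise or counter-clockwise of a reference and
    then, after trial feedback, estimate its orientation. Implements the
    conditioned-prior observer (decision, memory recall, estimation), five
    variants of post-feedback estimation on incorrect trials (prior-only,
    uncertainty-only heuristic, decision flip, feedback-consistent memory
    resampling, and surprise-reweighted likelihood), joint maximum-likelihood
    fitting of correct-trial data, parameter-free prediction of incorrect-trial
    estimate distributions, and model comparison against an omniscient
    empirical bound with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
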