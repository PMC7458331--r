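Package: seqbf
Title: Sequential Bayes Factors for Below-Chance Binary Outcomes with
    Monte Carlo Anomaly Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the sequential Bayesian analysis of multi-lab
    binary-outcome experiments in which each participant contributes a
    count of "negative" outcomes out of a fixed number of fair-bit
    trials.  Implements the one-sided one-sample Bayes factor under a
    scaled Cauchy prior on standardized effect size, sequential
    evidence trajectories with optional-stopping evaluation,
    prior-robustness sweeps, per-lab Bayes factors with a
    random-effects meta-analysis, and three temporal-anomaly statistics
    of an evidence trajectory (maximum Bayes factor, curve energy, and
    the sum of FFT amplitudes) calibrated against seeded Monte Carlo
    null simulations with empirical p-values.  A synthetic-cohort
    generator reproduces the trial-level XOR randomization scheme and
    the five-lab cohort structure of the motivating study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
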