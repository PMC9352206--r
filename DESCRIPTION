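Package: revattr
Title: Reversal Learning and Social Attribution Models for Paranoia Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational models of behaviour in two probabilistic reversal
    paradigms used in paranoia research: a three-option reversal-learning task
    modelled with Q-learning variants (Pearce-Hall salience, memory decay,
    reset-at-reversal, lapse), and a repeated-reversal Dictator game modelled
    with a discrete 9x9 Bayesian belief grid over a partner's harmful intent
    and self-interest, plus a comparator family of associative attribution
    models. Provides per-participant MAP fitting (Latin-hypercube grid scan,
    simulated annealing, quasi-Newton polish), BIC/AIC model comparison,
    parameter- and model-recovery analyses, model-agnostic behavioural
    statistics (win-switch/lose-stay rates, permutation Spearman correlations),
    and a synthetic cohort generator that couples paranoia scores to model
    parameters so that every analysis stage can be exercised without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
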