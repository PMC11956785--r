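Package: mmle
Title: Multimorbid Life Expectancy from Panel Data via Discrete-Time Multistate Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Incidence-based estimation of truncated life expectancy and
    multimorbid life expectancy (MMLE) from longitudinal panel data on
    chronic-disease status. Person-wave observations are classified into a
    four-state space (no disease, one disease, multimorbidity, death),
    sex-stratified design-weighted multinomial-logit models describe biennial
    transition probabilities as functions of age and covariates, and truncated
    state expectancies are computed through the fundamental matrix of the
    age-indexed absorbing Markov chain, with delta-method confidence
    intervals. Includes a synthetic-panel generator emulating the structure of
    the South African National Income Dynamics Study, a Monte Carlo trajectory
    oracle for validation, and sensitivity variants of the multimorbidity
    definition.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
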