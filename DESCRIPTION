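Package: cognilr
Title: Likelihood-Ratio Prognosis of Cognitive Decline in de Novo
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, evaluates and simulates transparent naive Bayes
    prognostic models of 2-4 year cognitive decline in newly diagnosed
    Parkinson's disease from baseline questionnaire data.  Clinical
    variables are binarized with predefined cutoffs, described by positive
    and negative likelihood ratios, combined with age-of-onset bracket
    prior probabilities into posterior probabilities of decline, pruned by
    sequential likelihood-ratio-test elimination and Jaccard redundancy
    filtering, and assessed by repeated random subsampling
    cross-validation with ROC/AUC summaries.  A synthetic-cohort
    generator with analytic oracles (implied likelihood ratios, exact
    model AUC by enumeration) stands in for the access-controlled study
    data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
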