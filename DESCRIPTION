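Package: ctxdep
Title: Quantifying Context-Dependency of Stimulus Effects on Multivariate
    Cellular Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for quantifying how much a stimulus's
    effect on multi-output cellular responses (e.g. cytokine secretion
    profiles) depends on the context in which the stimulus acts. Fits a
    random-intercept linear mixed model to stimulus-induced relative
    differences by maximum likelihood, tests context-dependency with
    likelihood-ratio tests, summarises it as a per-output score (mean
    pairwise distance between standard-error-rescaled per-context effects)
    with a quantitative/qualitative classification, computes multivariate
    stimulus-shift distances in principal-component space, and ranks
    competing context variables with a group-lasso regularization path.
    Includes detection-limit handling, chained-equations imputation, and a
    synthetic-data generator emulating the assumed data structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
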