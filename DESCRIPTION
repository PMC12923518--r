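Package: costlearn
Title: Learning Models and Choice Analysis for a Loss-Frame Probabilistic
    Task with Stable and Volatile Contexts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a two-context (stable/volatile) probabilistic
    loss-avoidance card task, fits Rescorla-Wagner, Sutton K1, and two- and
    three-level Hierarchical Gaussian Filter learning models with a softmax
    observation model carrying inverse temperature and loss sensitivity,
    compares models by random-effects Bayesian model selection with
    exceedance probabilities, and runs the stay/shift mixed-effects logistic
    regressions, simple-slopes follow-ups and parameter regressions used to
    relate task behaviour to substance-use severity. Includes a synthetic
    cohort generator with covariate-linked parameters for parameter, model
    and effect recovery studies, and a simulation-based power harness for
    cross-level interactions in mixed-effects logistic models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
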