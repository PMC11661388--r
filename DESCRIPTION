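Package: dotconf
Title: Decision and Confidence Models for Multi-Alternative Dot-Numerosity Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generative modelling and model comparison for three-choice
    dot-numerosity experiments in which observers report the dominant colour
    in a cloud of coloured dots and rate their confidence on a four-point
    scale. Internal activations follow scalar variability (a Gaussian whose
    mean and standard deviation are both proportional to the dot count), so a
    single noise parameter maps any number of stimulus conditions onto
    internal evidence distributions. The package implements the one- and
    four-parameter decision models (colour-bias multipliers and a lapse
    rate), three confidence computations (top-two evidence difference,
    Bayesian posterior probability of being correct, and positive evidence),
    maximum-likelihood fitting of joint choice-confidence distributions with
    AIC model comparison and bootstrap confidence intervals, a synthetic
    subject and cohort generator, and the condition-level behavioural
    contrasts (numerosity and non-dominant-options trade-off effects).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
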