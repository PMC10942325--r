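Package: tachycurve
Title: Tachometric Analysis of Urgent Pro- and Antisaccade Choices
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chronometric analysis of urgent saccadic choice experiments.
    Builds tachometric curves (fraction of correct choices as a function of
    raw processing time, rPT = RT - gap) from per-trial records or raw eye
    traces, fits sigmoid functions by mean-absolute-error minimisation to
    extract rise points and rPT-at-criterion values with bootstrap
    confidence intervals, quantifies exogenous attentional capture, guessing
    bias, motor bias and the antisaccade processing-time cost, and provides
    resampling-based inference (paired permutation, randomization, exact
    binomial and correlation-permutation tests). Includes a generative
    trial simulator with known ground truth so that every pipeline stage
    supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
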