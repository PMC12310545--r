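Package: apemodel
Title: Action Prediction Error Models of Striatal Dopamine Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for studying value-free action
    prediction error (APE) signals in tail-of-striatum dopamine. Implements a
    semi-Markov actor-critic reinforcement-learning agent with dwell-time
    scaled average-reward prediction errors and candidate dopamine signal
    models (RPE, APE, novelty, salience, movement), a dual value-based plus
    value-free controller network with lesion, psychometric and stimulation
    protocols, a cloud-of-tones two-alternative choice task simulator,
    fiber-photometry preprocessing (demodulation, filtering, isosbestic
    motion correction, dF/F) with event-kernel regression and per-regressor
    explained variance, behavioural statistics (Weibull learning curves,
    shuffle-null optogenetic bias tests, choice-history regressions,
    discrete Frechet trajectory similarity), and synthetic data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
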