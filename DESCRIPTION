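Package: gazemeta
Title: Meta-Learning Analysis of Infant Gaze Behaviour from Information Gain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how infants re-weight the informational value
    of visual events as they gain experience with a task. Implements an
    ideal-observer Dirichlet-categorical learner over probabilistic cue-target
    sequences and its trialwise Kullback-Leibler information gain, an
    exponential meta-learning weighting kernel with early up-weighting and
    late down-weighting across sequences, a hierarchical Bayesian observation
    model linking weighted information gain to three gaze measures (look-away,
    saccadic latency, looking time) fitted by MCMC, model comparison by WAIC
    and Pareto-smoothed importance-sampling LOO, a calibrated synthetic-cohort
    generator with look-away truncation and session dropout, and downstream
    analyses: unseen-sequence information-gain simulation and a mixed-effects
    learning-efficiency model for saccadic latencies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
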