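Package: rhlpmix
Title: Clustering Regime-Switching Multi-Subject Time Series with
    Mixtures of Regressions with Hidden Logistic Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simultaneous clustering of multi-subject univariate time
    series and segmentation of each series into smoothly switching
    regimes, using finite mixtures of polynomial regressions whose
    within-subject regime membership follows a time-indexed multinomial
    logistic process (mixRHLP). Provides maximum-likelihood estimation
    by a multi-start Expectation-Maximization algorithm with an
    iteratively reweighted least squares inner loop, model selection by
    BIC, sample-adjusted BIC, AIC and AICc over a grid of candidate
    models, maximum-a-posteriori cluster and regime classification with
    label-matched accuracy scoring, a generative simulator with
    missing-completely-at-random masking and linear-interpolation
    imputation for Monte Carlo study of the method, and a preprocessing
    pipeline (time rescaling, interval aggregation, winsorization) for
    irregularly sampled event streams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
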