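Package: cccausality
Title: Compression-Complexity Causality for Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-free, interventional causality estimation for time series
    using compression complexity. Implements the Effort-To-Compress (ETC)
    complexity measure based on Non-sequential Recursive Pair Substitution
    (NSRPS), for single symbol sequences and jointly for aligned pairs, and
    builds on it the Compression-Complexity Causality (CCC) estimator:
    windowed dynamical compression-complexities of a series given its own
    past, and given its own past together with a surgically constructed
    interventional block from a putative cause. Includes the conditional
    (multivariate) extension via dictionary encoding of symbol tuples,
    surrogate and t-test significance of the window-averaged causality,
    symmetric Kullback-Leibler and Jensen-Shannon divergence diagnostics,
    and seeded simulators for coupled autoregressive processes, coupled
    tent maps, and perturbations (non-uniform sampling, moving-average
    filtering, decimation) used to validate the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
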