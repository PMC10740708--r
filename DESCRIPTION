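Package: celldecide
Title: Decision-Theoretic Modeling of Cellular Signaling Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cellular decision-making errors in one-input,
    multi-output molecular signaling systems from single-cell measurements.
    Fits Gaussian models to log-transformed output concentrations under
    "low" versus "high" input hypotheses, solves the optimal likelihood-ratio
    decision thresholds (scalar roots in one dimension, decision threshold
    curves in two), and computes false-alarm, miss, and overall error
    probabilities by closed-form integration, Monte Carlo integration over
    decision regions, and empirical discriminant-function counting.
    Includes minimum-redundancy maximum-relevance (MRMR) output-importance
    scoring and a synthetic single-cell data generator emulating
    TNF-driven NF-kB/ATF-2 responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
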