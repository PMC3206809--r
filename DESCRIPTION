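Package: fibroscore
Title: High-Content Screening Scores for Anti-Fibrotic Drug Efficacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-cell high-content-screening feature distributions
    from hepatic stellate cell assays into drug efficacy scores. Per-cell
    feature distributions at each drug concentration are summarised against
    the drug-free control by a signed Kolmogorov-Smirnov score (unimodal
    features) or a positive-fraction ratio (bimodal features), integrated
    over the concentration series into a direction-corrected area-under-curve
    score per fibrosis marker (SAUC), and combined into a single in vitro
    efficacy predictor (E_predict) whose per-marker integer weights are
    optimised by exhaustive enumeration against literature-derived in vivo
    histology indices (E_in vivo) using an outlier-tolerant Spearman rank
    criterion. Includes a synthetic plate-screen simulator with known
    ground-truth efficacies, in vitro-in vivo regression with named-outlier
    handling, histological score prediction, marker/feature saturation and
    weight-robustness analyses, and PCA-based drug profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mclust,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
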