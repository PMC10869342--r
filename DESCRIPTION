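Package: ssnets
Title: Single-Sample Gene Coexpression Network Inference and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers single-sample (sample-specific) gene coexpression networks
    from bulk RNA-seq cohorts without normal-tissue reference samples, using six
    methods built on a common Pearson-correlation backbone: leave-one-out
    correlation perturbation (SSN), linear interpolation (LIONESS), weighted
    interpolation with genome-wide sample weights (SWEET), single-sample
    correlation from reference moments (iENA), a binary statistical-independence
    network (CSN), and rank-based edge perturbation against a background network
    (SSPGI). Includes the surrounding evaluation suite: expression preprocessing
    (CPM filtering, log-CPM, highly variable genes, per-gene scaling,
    cluster-based outlier removal), background-network pruning and top-k edge
    selection, node strength, network topology summaries, hub recurrence and
    subtype-specific hubs, driver-gene enrichment, empirical-Bayes differential
    node strength, correlation of node strengths to matched proteomics and
    copy-number data, and a synthetic cohort generator with planted coexpression
    modules, subtype-specific rewiring, and linked multi-omics for benchmarking.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
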