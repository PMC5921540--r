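Package: ampliconcna
Title: Copy Number Alteration Calling from Targeted Amplicon Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls somatic copy number gains and losses in tumor cohorts from
    targeted amplicon sequencing read-coverage matrices. Coverages are
    normalized by per-sample and per-amplicon medians to copy number
    estimates, a normal null centered at two copies with a MAD-calibrated
    spread is fitted per amplicon, one-sided outlier p-values are combined
    per gene with Fisher's method, and calls are made after family-wise
    error rate (Bonferroni) or false discovery rate (Benjamini-Hochberg)
    control over samples, genes, or both, with optional supporting-amplicon
    filters. Includes an intra-gene inconsistency quality statistic per
    sample, deterministic average-linkage heatmap ordering, ggplot2
    heatmaps, a purity-aware coverage cohort simulator with known truth,
    and an end-to-end pipeline with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
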