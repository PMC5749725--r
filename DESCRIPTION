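Package: mutsteps
Title: Somatic Mutation Analysis of Successive Steps of Tumor Progression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing somatic mutations across successive
    tumor samples (pre-invasive lesion, primary tumor, lymph-node and distant
    metastases) from the same patients. Implements multi-sample validation
    filtering of deep-sequencing variant calls with a low-allele-fraction
    rescue rule, partitioning of mutations into progression categories,
    non-synonymous to synonymous (NS:S) selection tests against the neutral
    2:1 expectation with exact one-tailed binomial p-values and driver-count
    estimation, recurrence tabulation within and across patients, gene-set
    over-representation by exact hypergeometric tests with Benjamini-Hochberg
    false discovery rate control, and rule-based triage of putative
    metastasis driver mutations. A synthetic multi-stage cohort generator
    with known clonal ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
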