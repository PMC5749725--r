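#!/usr/bin/env Rscript
# Stage 2: multi-sample validation filtering.
#
# Applies the validation criteria (normal BAF < 0.02, depth >= 50x in all
# samples, tumor BAF >= 0.05 in at least one sample, exonic/splicing only,
# population AF <= 1%, no curation flags) with the 0.025/200x rescue rule
# for presence in additional tumor samples, then checks the verdicts
# against the generator's ground truth.

library(mutsteps)

if (!file.exists("results/cohort.tsv")) {
  stop("stage 'filter' needs results/cohort.tsv; run 01_simulate_cohort.R first")
}
cohort <- read_variant_table("results/cohort.tsv")
truth <- read.delim("results/cohort_truth.tsv")

fr <- apply_filters(cohort, filter_config())
decisions <- fr$decisions
decisions$reasons <- vapply(decisions$reasons, paste, "", collapse = ",")
write.table(decisions, "results/filter_decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fr$presence, "results/presence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

report <- truth_compare(cohort, tibble::as_tibble(truth), filter_result = fr)
cat(sum(fr$decisions$verdict == "RETAINED"), "of",
    nrow(fr$decisions), "mutations retained\n")
cat(sprintf("  sensitivity vs ground truth: %.3f\n", report$filter$sensitivity))
cat(sprintf("  specificity vs ground truth: %.3f\n", report$filter$specificity))
cat("wrote results/filter_decisions.tsv and results/presence.tsv\n")
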