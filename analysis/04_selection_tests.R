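#!/usr/bin/env Rscript
# Stage 4: NS:S selection statistics.
#
# Per patient, the primary tumor's non-synonymous/synonymous SNV counts are
# tested against the neutral 2:1 expectation with the exact one-tailed
# binomial test, and the driver count estimated as the non-synonymous
# excess. Metastasis-specific mutations (axillary-node and distant,
# pooled across patients) are tested the same way.

library(mutsteps)

if (!file.exists("results/category_assignments.tsv")) {
  stop("stage 'select' needs results/category_assignments.tsv; run 03_progression_categories.R first")
}
cohort <- read_variant_table("results/cohort.tsv")
fr <- apply_filters(cohort, filter_config())

patients <- unique(cohort$samples$patient_id)
per_patient <- lapply(patients, function(pt) {
  ids <- intersect(mutations_in_stage(fr, "PRIMARY"),
                   cohort$mutations$mut_id[cohort$mutations$patient_id == pt])
  cnt <- count_classes(cohort, ids)
  selection_test(cnt[["ns"]], cnt[["s"]], label = paste0(pt, "_primary"))
})
pooled <- selection_test_groups(cohort, list(
  aln_specific = mutations_in_stage(fr, "ALN_MET", specific = TRUE),
  distant_specific = mutations_in_stage(fr, "DISTANT_MET", specific = TRUE)))

res <- dplyr::bind_rows(c(per_patient, list(pooled)))
res <- mutsteps:::new_result_tbl(res, "selection_test")
write_results(res, "results/selection_tests.tsv")

shown <- res
shown$ratio <- trunc_decimals(shown$ratio)
shown$p_value <- signif(shown$p_value, 2)
print(as.data.frame(shown), row.names = FALSE)
cat("\ndriver estimates range between", min(res$driver_estimate), "and",
    max(res$driver_estimate), "across groups\n")
cat("wrote results/selection_tests.tsv\n")
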