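#!/usr/bin/env Rscript
# Stage 3: progression categories, concordance and recurrence.
#
# Retained protein-altering mutations are partitioned into Category 1
# (exclusively DCIS/primary), Category 2 (shared between primary and
# metastases) and Category 3 (exclusively metastases); concordance patterns
# are tabulated per patient, and recurrently mutated genes listed within
# samples and across patients.

library(mutsteps)

if (!file.exists("results/filter_decisions.tsv")) {
  stop("stage 'categorize' needs results/filter_decisions.tsv; run 02_filter_variants.R first")
}
cohort <- read_variant_table("results/cohort.tsv")
fr <- apply_filters(cohort, filter_config())

asg <- categorize(cohort, fr)
write_results(asg, "results/category_assignments.tsv")
cat("category sizes:\n")
print(table(asg$category))

gene_sets <- category_gene_sets(asg)
cat("category gene-list sizes:",
    paste(names(gene_sets), lengths(gene_sets), sep = "=", collapse = ", "),
    "\n")

for (pt in unique(cohort$samples$patient_id)) {
  cc <- concordance_counts(cohort, fr, pt)
  cat("\nconcordance,", pt, "(pattern: n mutations)\n")
  print(as.data.frame(cc), row.names = FALSE)
}

rec <- recurrence(cohort, fr)
write_results(rec$within, "results/recurrence_within.tsv")
write_results(rec$across, "results/recurrence_across.tsv")
cat("\nrecurrently mutated:", nrow(rec$within),
    "(gene, patient, sample) entries with >= 2 distinct mutations;",
    nrow(rec$across), "genes mutated in >= 2 patients\n")
cat("wrote results/category_assignments.tsv, results/recurrence_*.tsv\n")
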