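#!/usr/bin/env Rscript
# Stage 1: generate the working cohort.
#
# Six patients, each with a matched normal and four successive tumor samples
# (DCIS, primary, axillary-node metastasis, distant metastasis), sequenced
# at validation depth (mean 465x). Per patient: 60 truncal mutations, 15
# private per stage, 20 drivers injected into the distant metastasis, plus
# 5% germline SNP and 3% repeat-artefact contamination for the filter to
# remove. Ground truth (clone, class, driver label) is kept alongside.

library(mutsteps)

seed <- 20260923L
dir.create("results", showWarnings = FALSE)

cfg <- cohort_sim_config(seed = seed, n_patients = 6,
                         n_truncal = 60, n_private = 15,
                         injected_drivers = c(DISTANT_MET = 20L),
                         pop_snp_rate = 0.05, blacklist_rate = 0.03)
sim <- simulate_cohort(cfg)

write_variant_table(sim$cohort, "results/cohort.tsv")
write.table(as.data.frame(sim$truth), "results/cohort_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("simulated", n_mutations(sim$cohort), "mutations across",
    length(unique(sim$cohort$samples$patient_id)), "patients\n")
cat("  germline SNP contaminants:", sum(sim$truth$is_pop_snp), "\n")
cat("  blacklist artefacts:      ", sum(sim$truth$blacklisted), "\n")
cat("  injected drivers:         ", sum(sim$truth$is_driver), "\n")
cat("wrote results/cohort.tsv and results/cohort_truth.tsv\n")
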