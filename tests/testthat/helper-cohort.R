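# Compact builders for small in-code cohorts.

# One row per observation; unspecified annotation columns get defaults.
build_cohort <- function(rows) {
  defaults <- list(patient = "P1", chrom = "1", ref = "A", alt = "G",
                   region_class = "EXONIC", consequence = "MISSENSE",
                   gene = "GENE1", pop_af = NA_real_, flags = NA_character_,
                   cdna_change = NA_character_, aa_change = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(rows)) rows[[nm]] <- defaults[[nm]]
  }
  mutsteps:::cohort_from_long(tibble::as_tibble(rows))
}

# A one-patient cohort with a normal and named tumor samples; each mutation
# is a list of per-sample c(depth, alt_reads) pairs keyed by sample name.
# muts: tibble(pos, <sample>_d, <sample>_a, ... [annotation cols])
one_patient <- function(stages, muts, patient = "P1") {
  ids <- c("N", names(stages))
  stage_of <- c(stats::setNames("NORMAL", "N"), stages)
  rows <- do.call(rbind, lapply(ids, function(smp) {
    stopifnot(!is.null(muts[[paste0(smp, "_d")]]))
    out <- muts
    out$sample <- smp
    out$stage <- unname(stage_of[smp])
    out$depth <- muts[[paste0(smp, "_d")]]
    out$alt_reads <- muts[[paste0(smp, "_a")]]
    out
  }))
  rows <- rows[, !grepl("_[da]$", names(rows))]
  rows$patient <- patient
  build_cohort(rows)
}

# Shorthand stage maps used across tests.
STG2 <- c(T1 = "PRIMARY", T2 = "DISTANT_MET")
STG3 <- c(D = "DCIS", T1 = "PRIMARY", M = "ALN_MET")

expect_retained <- function(fr, mut_ids) {
  d <- fr$decisions
  expect_setequal(d$mut_id[d$verdict == "RETAINED"], mut_ids)
}

reasons_of <- function(fr, mut_id) {
  fr$decisions$reasons[[match(mut_id, fr$decisions$mut_id)]]
}

presence_of <- function(fr, mut_id) {
  p <- fr$presence[fr$presence$mut_id == mut_id, ]
  stats::setNames(p$present, p$sample_id)[order(p$sample_id)]
}
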