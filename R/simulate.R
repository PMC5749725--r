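# Synthetic multi-stage tumor cohort generator with clonal ground truth.
#
# Emulates the study design the pipeline targets: per patient, a matched
# normal plus successive tumor samples (DCIS, primary, axillary-node
# metastasis, distant metastasis); truncal mutations present in every tumor
# sample and branch-private mutations confined to one stage's lineage.
# Consequence classes are drawn neutrally with a configurable
# non-synonymous fraction (2/3 by default, the flat neutral expectation),
# and a configurable number of driver mutations — all non-synonymous — is
# injected per stage. Read counts follow the sequencing model: depth per
# sample ~ negative binomial around the assay's mean coverage; alt reads ~
# binomial(depth, 0.5 * purity) where the clone is present (diploid
# heterozygous sites) and binomial(depth, error rate) elsewhere, the normal
# always at the error rate.

#' Configuration of the synthetic cohort generator
#'
#' @param seed integer seed; identical seed and config give identical output.
#' @param n_patients number of patients (default 6, the study size).
#' @param stages tumor stages sampled per patient (normal always included).
#' @param n_truncal truncal mutations per patient.
#' @param n_private named integer vector: branch-private mutations per stage
#'   (names must be a subset of `stages`), or a single unnamed count applied
#'   to every stage.
#' @param neutral_ns_fraction probability a neutral mutation is
#'   non-synonymous (default 2/3, the 2:1 neutral NS:S expectation).
#' @param missense_fraction within non-synonymous, the missense share
#'   (remainder stopgain; default 0.9).
#' @param injected_drivers named integer vector of driver mutations to
#'   inject per clone (`TRUNCAL` or a stage name); all non-synonymous.
#' @param mean_depth mean sequencing depth (default 465, deep targeted
#'   validation; use ~100 for exome-like data).
#' @param depth_dispersion negative-binomial size parameter (default 10).
#' @param purity tumor-cell fraction of tumor samples (default 0.8).
#' @param normal_error_rate per-read sequencing error rate (default 0.001).
#' @param pop_snp_rate fraction of simulated variants that are germline
#'   population SNPs (high BAF in all samples including the normal, with a
#'   population allele frequency above 1%).
#' @param blacklist_rate fraction of variants flagged as repeat-region
#'   artefacts.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(seed = 1L,
                              n_patients = 6L,
                              stages = c("DCIS", "PRIMARY", "ALN_MET",
                                         "DISTANT_MET"),
                              n_truncal = 60L,
                              n_private = 15L,
                              neutral_ns_fraction = 2/3,
                              missense_fraction = 0.9,
                              injected_drivers = integer(0),
                              mean_depth = 465L,
                              depth_dispersion = 10,
                              purity = 0.8,
                              normal_error_rate = 0.001,
                              pop_snp_rate = 0,
                              blacklist_rate = 0) {
  stopifnot(all(stages %in% TUMOR_STAGES), length(stages) >= 1L)
  if (is.null(names(n_private)) && length(n_private) == 1L) {
    n_private <- setNames(rep(as.integer(n_private), length(stages)), stages)
  }
  if (!all(names(n_private) %in% stages)) {
    abort("n_private names a stage the config does not sample")
  }
  if (length(injected_drivers) &&
      !all(names(injected_drivers) %in% c("TRUNCAL", stages))) {
    abort("injected_drivers names a clone outside TRUNCAL + sampled stages")
  }
  probs <- c(neutral_ns_fraction, missense_fraction, purity,
             normal_error_rate, pop_snp_rate, blacklist_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (depth_dispersion <= 0) abort("depth_dispersion must be positive")
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 stages = stages, n_truncal = as.integer(n_truncal),
                 n_private = n_private,
                 neutral_ns_fraction = neutral_ns_fraction,
                 missense_fraction = missense_fraction,
                 injected_drivers = injected_drivers,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion, purity = purity,
                 normal_error_rate = normal_error_rate,
                 pop_snp_rate = pop_snp_rate,
                 blacklist_rate = blacklist_rate),
            class = "cohort_sim_config")
}

#' Simulate a multi-stage cohort with ground truth
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (a [variant_cohort()]) and `truth` (tibble:
#'   `mut_id`, `patient_id`, `clone`, `consequence`, `is_driver`,
#'   `is_pop_snp`, `blacklisted`).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed, kind = "Mersenne-Twister")
  pieces <- lapply(seq_len(config$n_patients), function(p)
    simulate_patient(sprintf("PT%02d", p), config))
  cohort <- variant_cohort(
    bind_rows(lapply(pieces, `[[`, "samples")),
    bind_rows(lapply(pieces, `[[`, "mutations")),
    bind_rows(lapply(pieces, `[[`, "observations")))
  truth <- bind_rows(lapply(pieces, `[[`, "truth")) %>%
    arrange(.data$mut_id)
  list(cohort = cohort, truth = truth)
}

simulate_patient <- function(patient_id, config) {
  stages <- config$stages
  samples <- tibble(
    patient_id = patient_id,
    sample_id = paste0(patient_id, "_", c("NORMAL", stages)),
    stage = c("NORMAL", stages))

  # clone labels per mutation: truncal, stage-private, then injected drivers
  clone <- c(rep("TRUNCAL", config$n_truncal),
             rep(names(config$n_private), config$n_private))
  is_driver <- rep(FALSE, length(clone))
  if (length(config$injected_drivers)) {
    clone <- c(clone, rep(names(config$injected_drivers),
                          config$injected_drivers))
    is_driver <- c(is_driver, rep(TRUE, sum(config$injected_drivers)))
  }
  n_mut <- length(clone)
  if (!n_mut) {
    return(list(samples = samples, mutations = empty_mutations(),
                observations = empty_observations(),
                truth = tibble(mut_id = character(), patient_id = character(),
                               clone = character(), consequence = character(),
                               is_driver = logical(), is_pop_snp = logical(),
                               blacklisted = logical())))
  }

  # neutral consequence classes; drivers forced non-synonymous
  u <- runif(n_mut)
  consequence <- ifelse(u < config$neutral_ns_fraction,
                        ifelse(runif(n_mut) < config$missense_fraction,
                               "MISSENSE", "STOPGAIN"),
                        "SYNONYMOUS")
  consequence[is_driver] <- ifelse(
    runif(sum(is_driver)) < config$missense_fraction, "MISSENSE", "STOPGAIN")

  is_pop_snp <- runif(n_mut) < config$pop_snp_rate
  blacklisted <- runif(n_mut) < config$blacklist_rate

  chrom <- as.character(sample.int(22L, n_mut, replace = TRUE))
  pos <- sample.int(100000000L, n_mut, replace = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_mut, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  gene <- sprintf("GENE%04d", sample.int(5000L, n_mut, replace = TRUE))
  mut_id <- mutation_key(patient_id, chrom, pos, ref, alt)

  mutations <- tibble(
    patient_id = patient_id, mut_id = mut_id, gene = gene,
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    region_class = "EXONIC", consequence = consequence,
    cdna_change = NA_character_, aa_change = NA_character_,
    pop_af = ifelse(is_pop_snp, runif(n_mut, 0.02, 0.5), NA_real_),
    flags = lapply(blacklisted, function(b) if (b) "REPEAT_REGION" else character(0)))

  # presence of each clone in each sample; pop SNPs are germline (everywhere)
  present_in <- function(cl, stage) {
    stage != "NORMAL" & (cl == "TRUNCAL" | cl == stage)
  }
  obs <- lapply(seq_len(nrow(samples)), function(si) {
    stage <- samples$stage[si]
    carried <- present_in(clone, stage) | is_pop_snp
    vaf <- ifelse(carried,
                  ifelse(is_pop_snp, 0.5,
                         ifelse(stage == "NORMAL", config$normal_error_rate,
                                0.5 * config$purity)),
                  config$normal_error_rate)
    depth <- rnbinom(n_mut, mu = config$mean_depth,
                     size = config$depth_dispersion)
    tibble(mut_id = mut_id, sample_id = samples$sample_id[si],
           depth = depth, alt_reads = rbinom(n_mut, depth, vaf))
  })

  truth <- tibble(mut_id = mut_id, patient_id = patient_id, clone = clone,
                  consequence = consequence, is_driver = is_driver,
                  is_pop_snp = is_pop_snp, blacklisted = blacklisted)
  list(samples = samples, mutations = mutations,
       observations = bind_rows(obs), truth = truth)
}

#' Compare pipeline outputs against simulation ground truth
#'
#' @param cohort the simulated [variant_cohort()].
#' @param truth the ground-truth tibble from [simulate_cohort()].
#' @param filter_result optional [apply_filters()] result; yields filter
#'   sensitivity (true somatic mutations retained) and specificity
#'   (pop-SNP/artefact entries rejected).
#' @param assignments optional [categorize()] result; yields the confusion
#'   matrix of expected vs assigned categories (truncal mutations are
#'   expected in Category 2 when the patient has metastasis samples,
#'   early-private in Category 1, metastasis-private in Category 3).
#' @param selection optional [selection_test()] result tibble; compared
#'   against the number of injected drivers.
#' @return list with `filter`, `categories` (list: `confusion`, `accuracy`)
#'   and `drivers` components (NULL where input was not supplied); empty
#'   list-shaped report for an empty cohort.
#' @export
truth_compare <- function(cohort, truth, filter_result = NULL,
                          assignments = NULL, selection = NULL) {
  if (!setequal(truth$mut_id, cohort$mutations$mut_id)) {
    abort("ground truth and cohort describe different mutation sets")
  }
  report <- list(filter = NULL, categories = NULL, drivers = NULL)
  if (!nrow(truth)) return(report)

  if (!is.null(filter_result)) {
    d <- filter_result$decisions %>% left_join(truth, by = "mut_id")
    true_somatic <- !d$is_pop_snp & !d$blacklisted
    retained <- d$verdict == "RETAINED"
    report$filter <- tibble(
      sensitivity = if (any(true_somatic))
        mean(retained[true_somatic]) else NA_real_,
      specificity = if (any(!true_somatic))
        mean(!retained[!true_somatic]) else NA_real_)
  }

  if (!is.null(assignments)) {
    pat_has_met <- cohort$samples %>%
      group_by(.data$patient_id) %>%
      summarise(has_met = any(.data$stage %in% MET_STAGES), .groups = "drop")
    expected <- truth %>%
      left_join(pat_has_met, by = "patient_id") %>%
      mutate(expected_category = dplyr::case_when(
        .data$clone == "TRUNCAL" & .data$has_met ~ "CAT2_SHARED",
        .data$clone == "TRUNCAL" ~ "CAT1_EARLY_ONLY",
        .data$clone %in% c("DCIS", "PRIMARY") ~ "CAT1_EARLY_ONLY",
        TRUE ~ "CAT3_MET_ONLY")) %>%
      select("mut_id", "expected_category")
    joined <- assignments %>% inner_join(expected, by = "mut_id")
    confusion <- joined %>%
      count(.data$expected_category, .data$category, name = "n")
    report$categories <- list(
      confusion = confusion,
      accuracy = mean(joined$category == joined$expected_category))
  }

  if (!is.null(selection)) {
    injected <- sum(truth$is_driver)
    report$drivers <- tibble(
      injected = injected,
      driver_estimate = sum(selection$driver_estimate),
      bias = sum(selection$driver_estimate) - injected)
  }
  report
}
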