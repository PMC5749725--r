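# Progression-category partitioning, per-patient concordance counts and
# recurrence tables.
#
# Validated protein-altering mutations fall into three categories by where
# along the progression they are seen (post-rescue presence): Category 1,
# exclusively in pre-invasive/primary tissue; Category 2, shared between
# primary tumors and metastases; Category 3, exclusively in metastases.

PROGRESSION_CATEGORIES <- c("CAT1_EARLY_ONLY", "CAT2_SHARED", "CAT3_MET_ONLY")

#' Assign progression categories to retained mutations
#'
#' Uses the post-rescue presence vectors from [apply_filters()]. A mutation
#' present in at least one early sample (DCIS or primary) and no metastasis
#' sample is Category 1; present in at least one early and at least one
#' metastasis sample (axillary-node or distant) is Category 2; present only
#' in metastasis samples is Category 3. The three categories partition the
#' retained mutations of the included consequence classes.
#'
#' @param cohort a [variant_cohort()] (the unfiltered cohort is fine; only
#'   retained mutations are categorised).
#' @param filter_result result of [apply_filters()] on `cohort`.
#' @param classes consequence classes to include; defaults to the
#'   protein-altering classes (everything but SYNONYMOUS and OTHER).
#' @return a result tibble (`mut_id`, `patient_id`, `gene`, `category`, one
#'   logical column per stage with any presence).
#' @export
categorize <- function(cohort, filter_result, classes = PROTEIN_ALTERING) {
  stage_presence <- filter_result$presence %>%
    group_by(.data$mut_id, .data$stage) %>%
    summarise(present = any(.data$present), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "stage", values_from = "present",
                       values_fill = FALSE)
  for (st in TUMOR_STAGES) {
    if (!st %in% names(stage_presence)) stage_presence[[st]] <- FALSE
  }

  muts <- cohort$mutations %>%
    filter(.data$consequence %in% classes) %>%
    select("mut_id", "patient_id", "gene") %>%
    inner_join(stage_presence, by = "mut_id")

  early <- muts$DCIS | muts$PRIMARY
  met <- muts$ALN_MET | muts$DISTANT_MET
  if (any(!early & !met)) {
    bad <- muts$mut_id[!early & !met][1]
    abort(paste0("mutation with empty tumor presence cannot be categorised: ",
                 bad))
  }
  muts$category <- dplyr::case_when(
    early & !met ~ "CAT1_EARLY_ONLY",
    early & met ~ "CAT2_SHARED",
    TRUE ~ "CAT3_MET_ONLY")

  new_result_tbl(
    muts %>% select("mut_id", "patient_id", "gene", "category",
                    all_of(TUMOR_STAGES)),
    "category_assignment")
}

#' Genes mutated in each progression category
#'
#' Gene-level view of [categorize()] for over-representation analysis: a
#' gene mutated twice counts once. A gene can appear in more than one
#' category (through different mutations or different patients).
#'
#' @param assignments result of [categorize()].
#' @return named list of uppercased gene-symbol vectors, one per category.
#' @export
category_gene_sets <- function(assignments) {
  out <- lapply(PROGRESSION_CATEGORIES, function(cat) {
    sort(unique(toupper(assignments$gene[assignments$category == cat])))
  })
  setNames(out, PROGRESSION_CATEGORIES)
}

#' Concordance counts over the tumor-sample presence patterns of a patient
#'
#' The Venn-partition counts behind multi-sample concordance diagrams: for
#' every non-empty subset of a patient's tumor samples, the number of
#' retained mutations present in exactly that subset.
#'
#' @param cohort a [variant_cohort()].
#' @param filter_result result of [apply_filters()].
#' @param patient patient identifier; must have at least two tumor samples.
#' @param classes consequence classes counted (default protein-altering,
#'   matching the non-synonymous + splice-site convention of concordance
#'   figures).
#' @return tibble (`pattern`, `n`): `pattern` is the sorted, `+`-joined set
#'   of sample ids. Patterns sum to the number of distinct retained
#'   mutations of the patient with any tumor presence.
#' @export
concordance_counts <- function(cohort, filter_result, patient,
                               classes = PROTEIN_ALTERING) {
  tumor_samples <- cohort$samples %>%
    filter(.data$patient_id == patient, .data$stage != "NORMAL")
  if (nrow(tumor_samples) < 2L) {
    abort("concordance requires at least two tumor samples for the patient")
  }
  keep <- cohort$mutations %>%
    filter(.data$patient_id == patient, .data$consequence %in% classes)
  pat <- filter_result$presence %>%
    filter(.data$mut_id %in% keep$mut_id, .data$present) %>%
    group_by(.data$mut_id) %>%
    summarise(pattern = paste(sort(.data$sample_id), collapse = "+"),
              .groups = "drop")
  pat %>% count(.data$pattern, name = "n") %>% arrange(.data$pattern)
}

#' Recurrently mutated genes within samples and across patients
#'
#' The within-patient view lists (gene, patient, sample) combinations
#' carrying at least `min_within` distinct protein-altering mutations
#' (distinct genomic variants, not reads), with the multiplicity rendered in
#' `2x`/`3x` notation. The across-patients view lists genes mutated in at
#' least `min_across` patients.
#'
#' @param cohort a [variant_cohort()] (typically the retained cohort).
#' @param filter_result result of [apply_filters()] on the cohort the ids
#'   refer to; presence determines which samples carry a mutation.
#' @param min_within minimum distinct mutations per (gene, patient, sample).
#' @param min_across minimum number of mutated patients per gene.
#' @param classes consequence classes included (default protein-altering;
#'   synonymous-only genes never appear).
#' @return list with `within` and `across` result tibbles.
#' @export
recurrence <- function(cohort, filter_result, min_within = 2L,
                       min_across = 2L, classes = PROTEIN_ALTERING) {
  keep <- cohort$mutations %>% filter(.data$consequence %in% classes)
  present <- filter_result$presence %>%
    filter(.data$present, .data$mut_id %in% keep$mut_id) %>%
    left_join(select(keep, "mut_id", "gene", "patient_id"), by = "mut_id")

  within <- present %>%
    group_by(gene = .data$gene, patient_id = .data$patient_id,
             sample_id = .data$sample_id) %>%
    summarise(multiplicity = n_distinct(.data$mut_id), .groups = "drop") %>%
    filter(.data$multiplicity >= min_within) %>%
    mutate(label = paste0(.data$multiplicity, "x")) %>%
    arrange(dplyr::desc(.data$multiplicity), .data$gene)

  across_tbl <- present %>%
    distinct(.data$gene, .data$patient_id) %>%
    count(.data$gene, name = "n_patients") %>%
    filter(.data$n_patients >= min_across) %>%
    arrange(dplyr::desc(.data$n_patients), .data$gene)

  list(within = new_result_tbl(within, "recurrence_within"),
       across = new_result_tbl(across_tbl, "recurrence_across"))
}
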