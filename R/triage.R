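# Rule-based triage of putative progression-driver mutations.
#
# A mutation from the shared (Category 2) or metastasis-specific
# (Category 3) compartment qualifies as a putative progression driver iff it
# is truncating or splice-disrupting (frameshift, stopgain, splice site), or
# a per-mutation driver score flags it. The scoring model is pluggable: any
# function mapping mutations to (score, is_driver) works, the bundled
# default reads a precomputed score table, and a conservative fallback
# flags nothing so that only the truncating rule fires. Gene-list
# membership (cancer gene census, cancer-pathway lists) is annotation only,
# never a qualifying criterion.

TRUNCATING_CLASSES <- c("FRAMESHIFT_INS", "FRAMESHIFT_DEL", "STOPGAIN",
                        "SPLICE_SITE")

#' Build a scorer from a precomputed score table
#'
#' The table is a TSV with columns `chrom`, `pos`, `ref`, `alt`, `score`,
#' `is_driver` (TRUE/FALSE); mutations absent from the table get an NA
#' score and are not flagged.
#'
#' @param path path to the score TSV.
#' @return a scorer: `function(mutations_tibble) -> tibble(score, is_driver)`.
#' @export
scorer_from_table <- function(path) {
  tab <- as_tibble(read.delim(path, sep = "\t", quote = "",
                              stringsAsFactors = FALSE))
  needed <- c("chrom", "pos", "ref", "alt", "score", "is_driver")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    abort(paste0("score table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab$is_driver <- as.logical(tab$is_driver)
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  function(muts) {
    hit <- muts %>%
      left_join(tab, by = c("chrom", "pos", "ref", "alt"))
    tibble(score = hit$score,
           is_driver = !is.na(hit$is_driver) & hit$is_driver)
  }
}

#' Conservative fallback scorer: flags no mutation
#'
#' With this scorer only the truncating/splice rule selects drivers.
#'
#' @param muts mutations tibble.
#' @return tibble(score = NA, is_driver = FALSE) per row.
#' @export
scorer_truncating_only <- function(muts) {
  tibble(score = rep(NA_real_, nrow(muts)),
         is_driver = rep(FALSE, nrow(muts)))
}

#' Triage putative progression-driver mutations
#'
#' @param assignments result of [categorize()].
#' @param cohort the [variant_cohort()] the assignments refer to.
#' @param scorer a scorer function (see [scorer_from_table()]); default
#'   [scorer_truncating_only].
#' @param gene_lists optional named list of gene-symbol vectors (e.g.
#'   `list(COSMIC_CGC = ..., KEGG_CANCER = ...)`); membership is reported as
#'   annotation columns.
#' @param categories progression categories triaged (default Categories 2
#'   and 3).
#' @return result tibble of driver calls: `mut_id`, `patient_id`, `gene`,
#'   `category`, `consequence`, `rule` (TRUNCATING_OR_SPLICE or
#'   SCORE_DRIVER), `score`, per-gene-list membership flags, and
#'   per-metastasis presence (`ALN_MET`, `DISTANT_MET`).
#' @export
triage <- function(assignments, cohort, scorer = scorer_truncating_only,
                   gene_lists = list(),
                   categories = c("CAT2_SHARED", "CAT3_MET_ONLY")) {
  cand <- assignments %>%
    filter(.data$category %in% categories) %>%
    left_join(select(cohort$mutations, "mut_id", "chrom", "pos", "ref",
                     "alt", "consequence"),
              by = "mut_id")
  if (!nrow(cand)) {
    return(new_result_tbl(
      tibble(mut_id = character(), patient_id = character(),
             gene = character(), category = character(),
             consequence = character(), rule = character(),
             score = numeric(), ALN_MET = logical(),
             DISTANT_MET = logical()),
      "driver_call"))
  }
  scored <- scorer(cand)
  truncating <- cand$consequence %in% TRUNCATING_CLASSES
  flagged <- scored$is_driver
  qualifies <- truncating | flagged

  calls <- cand %>%
    mutate(rule = dplyr::case_when(
      truncating ~ "TRUNCATING_OR_SPLICE",
      flagged ~ "SCORE_DRIVER",
      TRUE ~ NA_character_),
      score = scored$score) %>%
    filter(qualifies) %>%
    select("mut_id", "patient_id", "gene", "category", "consequence",
           "rule", "score", "ALN_MET", "DISTANT_MET")
  for (nm in names(gene_lists)) {
    calls[[nm]] <- toupper(calls$gene) %in% toupper(gene_lists[[nm]])
  }
  new_result_tbl(calls, "driver_call")
}

#' Per-category driver-call totals
#'
#' @param calls result of [triage()].
#' @return tibble (`category`, `n_mutations`, `n_genes`); distinct genes
#'   never exceed mutations.
#' @export
summarize_counts <- function(calls) {
  if (!nrow(calls)) {
    return(tibble(category = character(), n_mutations = integer(),
                  n_genes = integer()))
  }
  calls %>%
    group_by(.data$category) %>%
    summarise(n_mutations = n_distinct(.data$mut_id),
              n_genes = n_distinct(.data$gene), .groups = "drop")
}
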