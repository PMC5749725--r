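# Multi-sample validation filtering of deep-sequencing variant calls.
#
# The criteria mirror a targeted-deep-sequencing validation step run per
# patient: the matched normal must be clean (BAF < 0.02), every sample must
# be adequately covered (>= 50x), and at least one tumor sample must show
# real signal (BAF >= 0.05). A mutation established that way is additionally
# scored "present" in further tumor samples at a relaxed BAF of 0.025
# provided depth there exceeds 200x (the rescue rule). Region-class
# restriction, population-SNP exclusion and curation flags/blacklist then
# remove annotation-level artefacts.

#' Filter configuration
#'
#' Thresholds for [apply_filters()]. Boundary semantics follow the wording
#' of the validation criteria literally: normal BAF strictly below
#' `normal_baf_max`; depth at least `min_depth_all` in every sample
#' (inclusive); best tumor BAF at least `tumor_baf_min` (inclusive); the
#' rescue rule requires BAF at least `rescue_baf_min` and depth strictly
#' greater than `rescue_depth_min`.
#'
#' @param normal_baf_max maximum tolerated BAF in the matched normal
#'   (exclusive bound; default 0.02).
#' @param min_depth_all minimum read depth required in every sample,
#'   normal included (inclusive; default 50).
#' @param tumor_baf_min minimum BAF required in at least one tumor sample
#'   (inclusive; default 0.05).
#' @param rescue_baf_min relaxed BAF bound for presence in additional tumor
#'   samples (inclusive; default 0.025).
#' @param rescue_depth_min depth a sample must exceed for the rescue rule to
#'   apply (exclusive; default 200).
#' @param pop_af_max population allele frequency above which a variant is a
#'   known SNP and excluded (exclusive bound; default 0.01).
#' @param allowed_regions region classes retained (default exonic and
#'   splicing).
#' @param adjacent_cluster_window,adjacent_cluster_count window (bp) and
#'   minimum variant count for [flag_clusters()].
#' @return a `filter_config` list.
#' @export
filter_config <- function(normal_baf_max = 0.02,
                          min_depth_all = 50L,
                          tumor_baf_min = 0.05,
                          rescue_baf_min = 0.025,
                          rescue_depth_min = 200L,
                          pop_af_max = 0.01,
                          allowed_regions = c("EXONIC", "SPLICING"),
                          adjacent_cluster_window = 10L,
                          adjacent_cluster_count = 3L) {
  if (rescue_baf_min > tumor_baf_min) {
    abort("rescue_baf_min must not exceed tumor_baf_min")
  }
  vals <- c(normal_baf_max, min_depth_all, tumor_baf_min, rescue_baf_min,
            rescue_depth_min, pop_af_max)
  if (any(vals < 0)) abort("thresholds must be non-negative")
  structure(list(normal_baf_max = normal_baf_max,
                 min_depth_all = as.integer(min_depth_all),
                 tumor_baf_min = tumor_baf_min,
                 rescue_baf_min = rescue_baf_min,
                 rescue_depth_min = as.integer(rescue_depth_min),
                 pop_af_max = pop_af_max,
                 allowed_regions = allowed_regions,
                 adjacent_cluster_window = as.integer(adjacent_cluster_window),
                 adjacent_cluster_count = as.integer(adjacent_cluster_count)),
            class = "filter_config")
}

#' Read a filter configuration from a key=value text file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored;
#' `allowed_regions` comma-separated. Unknown keys are an error.
#'
#' @param path path to the config file.
#' @return a [filter_config()].
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  args <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]
    if (!key %in% names(formals(filter_config))) {
      abort(paste0("unknown filter config key: ", key))
    }
    args[[key]] <- if (key == "allowed_regions") {
      trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]])
    } else {
      as.numeric(vals[i])
    }
  }
  do.call(filter_config, args)
}

# Reason codes, in the order they are evaluated and reported.
REASON_CODES <- c("NORMAL_CONTAMINATION", "LOW_DEPTH", "NO_TUMOR_SIGNAL",
                  "REGION_EXCLUDED", "POPULATION_SNP", "BLACKLISTED",
                  "CLUSTERED")

#' Apply the multi-sample validation criteria to a cohort
#'
#' Each mutation is retained iff all of the following hold: matched-normal
#' BAF strictly below `normal_baf_max`; depth at least `min_depth_all` in
#' every sample of the patient; BAF at least `tumor_baf_min` in at least one
#' tumor sample; region class among `allowed_regions`; population allele
#' frequency missing or not above `pop_af_max`; not in the blacklist and not
#' carrying a curation flag. For retained mutations, per-tumor-sample
#' presence applies the rescue rule: a tumor sample counts as carrying the
#' mutation if its BAF reaches `tumor_baf_min`, or if its BAF reaches
#' `rescue_baf_min` and its depth exceeds `rescue_depth_min`.
#'
#' @param cohort a [variant_cohort()]; every mutation must have an
#'   observation in its patient's normal sample.
#' @param config a [filter_config()].
#' @param blacklist optional tibble of 1-based closed intervals
#'   (`chrom`, `start`, `end`), e.g. from [read_bed_blacklist()].
#' @return a `filter_result`: list with `decisions` (tibble: `mut_id`,
#'   `verdict` RETAINED/REJECTED, `reasons` list column) and `presence`
#'   (tibble: `mut_id`, `sample_id`, `stage`, `present` for tumor samples of
#'   retained mutations).
#' @export
apply_filters <- function(cohort, config = filter_config(), blacklist = NULL) {
  muts <- cohort$mutations
  if (!nrow(muts)) {
    return(structure(list(
      decisions = tibble(mut_id = character(), verdict = character(),
                         reasons = list()),
      presence = tibble(mut_id = character(), sample_id = character(),
                        stage = character(), present = logical())),
      class = "filter_result"))
  }
  obs <- obs_with_stage(cohort)

  normals <- obs %>% filter(.data$stage == "NORMAL")
  missing_normal <- setdiff(muts$mut_id, normals$mut_id)
  if (length(missing_normal)) {
    abort(paste0("mutation(s) lacking a normal observation: ",
                 paste(head(missing_normal, 3), collapse = ", ")))
  }

  per_mut <- obs %>%
    group_by(.data$mut_id) %>%
    summarise(
      normal_baf = .data$baf[.data$stage == "NORMAL"][1],
      min_depth = min(.data$depth),
      max_tumor_baf = {
        tb <- .data$baf[.data$stage != "NORMAL"]
        if (all(is.na(tb))) NA_real_ else max(tb, na.rm = TRUE)
      },
      .groups = "drop")

  black <- blacklist_hits(muts, blacklist)
  flagged <- vapply(muts$flags, function(f)
    any(c("REPEAT_REGION", "ERROR_PRONE_REGION") %in% f), logical(1))
  clustered <- vapply(muts$flags, function(f) "ADJACENT_CLUSTER" %in% f,
                      logical(1))

  d <- muts %>%
    select("mut_id", "region_class", "pop_af") %>%
    left_join(per_mut, by = "mut_id") %>%
    mutate(
      r_normal = is.na(.data$normal_baf) | .data$normal_baf >= config$normal_baf_max,
      r_depth = .data$min_depth < config$min_depth_all,
      r_signal = is.na(.data$max_tumor_baf) |
        .data$max_tumor_baf < config$tumor_baf_min,
      r_region = !.data$region_class %in% config$allowed_regions,
      r_snp = !is.na(.data$pop_af) & .data$pop_af > config$pop_af_max,
      r_black = black | flagged,
      r_clust = clustered)

  reason_mat <- cbind(d$r_normal, d$r_depth, d$r_signal, d$r_region,
                      d$r_snp, d$r_black, d$r_clust)
  colnames(reason_mat) <- REASON_CODES
  reasons <- apply(reason_mat, 1L, function(r) REASON_CODES[r],
                   simplify = FALSE)
  decisions <- tibble(
    mut_id = d$mut_id,
    verdict = if_else(lengths(reasons) == 0L, "RETAINED", "REJECTED"),
    reasons = reasons)

  retained <- decisions$mut_id[decisions$verdict == "RETAINED"]
  presence <- obs %>%
    filter(.data$stage != "NORMAL", .data$mut_id %in% retained) %>%
    mutate(present = sample_presence(.data$baf, .data$depth, config)) %>%
    select("mut_id", "sample_id", "stage", "present")

  structure(list(decisions = decisions, presence = presence),
            class = "filter_result")
}

# Rescue rule: full-threshold BAF, or relaxed BAF at deep coverage.
sample_presence <- function(baf, depth, config) {
  (!is.na(baf) & baf >= config$tumor_baf_min) |
    (!is.na(baf) & baf >= config$rescue_baf_min &
       depth > config$rescue_depth_min)
}

blacklist_hits <- function(muts, blacklist) {
  if (is.null(blacklist) || !nrow(blacklist)) {
    return(rep(FALSE, nrow(muts)))
  }
  vapply(seq_len(nrow(muts)), function(i) {
    any(blacklist$chrom == muts$chrom[i] &
          blacklist$start <= muts$pos[i] &
          blacklist$end >= muts$pos[i])
  }, logical(1))
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", sum(x$decisions$verdict == "RETAINED"), "/",
      nrow(x$decisions), " mutations retained\n", sep = "")
  invisible(x)
}

#' Flag mutations sitting in dense local clusters
#'
#' Clusters of adjacent variants are a signature of systematic misalignment;
#' any mutation with at least `count - 1` other mutations of the same
#' patient within `window` bp on the same chromosome receives the
#' `ADJACENT_CLUSTER` curation flag.
#'
#' @param cohort a [variant_cohort()].
#' @param window window half-width in bp (default from `config`).
#' @param count minimum number of variants (the mutation itself included)
#'   that makes a cluster.
#' @return the cohort with updated `flags`.
#' @export
flag_clusters <- function(cohort, window = 10L, count = 3L) {
  muts <- cohort$mutations
  if (!nrow(muts)) return(cohort)
  neighbour_counts <- muts %>%
    group_by(.data$patient_id, .data$chrom) %>%
    mutate(n_near = vapply(.data$pos, function(p)
      sum(abs(.data$pos - p) <= window), integer(1))) %>%
    ungroup() %>%
    pull(.data$n_near)
  hit <- neighbour_counts >= count
  muts$flags <- lapply(seq_len(nrow(muts)), function(i) {
    f <- setdiff(muts$flags[[i]], "ADJACENT_CLUSTER")
    if (hit[i]) f <- c(f, "ADJACENT_CLUSTER")
    sort(f)
  })
  variant_cohort(cohort$samples, muts, cohort$observations)
}

#' Retained subset of a cohort after filtering
#'
#' @param cohort a [variant_cohort()].
#' @param filter_result result of [apply_filters()].
#' @return the cohort restricted to RETAINED mutations.
#' @export
retained_cohort <- function(cohort, filter_result) {
  keep <- filter_result$decisions$mut_id[
    filter_result$decisions$verdict == "RETAINED"]
  subset_cohort(cohort, keep)
}
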