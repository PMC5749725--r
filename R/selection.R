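# NS:S ratio selection statistics.
#
# Under neutrality, non-synonymous and synonymous point mutations persist in
# proportion to their rate of creation, which for the coding genome gives an
# expected NS:S ratio of about 2:1. An excess of non-synonymous mutations
# over that expectation indicates positive selection, and the size of the
# excess estimates how many of the mutations are drivers. The test is an
# exact one-tailed binomial: with n = NS + S observed coding SNVs and a
# neutral non-synonymous fraction p0 = 2/3, the p-value is
# P(X >= NS) for X ~ Binomial(n, p0).

#' Exact upper tail of the binomial distribution
#'
#' Computes `P(X >= k)` for `X ~ Binomial(n, p0)` by exact summation of the
#' probability mass function, with each term evaluated in log space
#' (`lchoose(n, j) + j log p0 + (n - j) log(1 - p0)`) so that extreme tails
#' do not underflow term by term. The smaller tail is summed and
#' complemented when that is cheaper.
#'
#' @param k integer, number of successes (vectorised).
#' @param n integer, number of trials.
#' @param p0 success probability, strictly between 0 and 1.
#' @return `P(X >= k)`, exact to floating-point summation accuracy.
#' @export
#' @examples
#' binom_tail_exact(2, 2, 2/3)   # (2/3)^2
#' binom_tail_exact(177, 224, 2/3)
binom_tail_exact <- function(k, n, p0) {
  if (length(n) == 1L) n <- rep(n, length(k))
  if (length(k) != length(n)) abort("k and n lengths differ")
  if (any(k < 0) || any(n < 0) || any(k > n)) {
    abort("need 0 <= k <= n")
  }
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly in (0, 1)")
  vapply(seq_along(k), function(i) {
    ki <- k[i]; ni <- n[i]
    if (ki == 0L) return(1)
    upper <- ni - ki + 1L          # number of terms in P(X >= k)
    if (upper <= ki) {             # sum the upper tail directly
      j <- ki:ni
      sum(exp(lchoose(ni, j) + j * log(p0) + (ni - j) * log1p(-p0)))
    } else {                       # sum the complement P(X <= k-1)
      j <- 0:(ki - 1L)
      lower <- sum(exp(lchoose(ni, j) + j * log(p0) + (ni - j) * log1p(-p0)))
      max(1 - lower, 0)
    }
  }, numeric(1))
}

#' Count non-synonymous and synonymous SNVs in a mutation set
#'
#' NS counts single-nucleotide variants of consequence MISSENSE, STOPGAIN or
#' STOPLOSS; S counts SYNONYMOUS SNVs. Splice-site mutations and indels are
#' excluded from both by default — the ratio's neutral 2:1 expectation is a
#' statement about coding point mutations — but can be folded into NS for
#' sensitivity analysis.
#'
#' @param cohort a [variant_cohort()].
#' @param mut_ids optional character vector restricting the count to a
#'   mutation subset (e.g. a progression category or a stage-specific group);
#'   default all mutations in the cohort.
#' @param include_splice_in_ns count SPLICE_SITE mutations as NS (default
#'   FALSE).
#' @param include_indels_in_ns count frameshift/non-frameshift indels as NS
#'   (default FALSE).
#' @return named integer vector `c(ns = , s = )`.
#' @export
count_classes <- function(cohort, mut_ids = NULL,
                          include_splice_in_ns = FALSE,
                          include_indels_in_ns = FALSE) {
  muts <- cohort$mutations
  if (!is.null(mut_ids)) muts <- filter(muts, .data$mut_id %in% mut_ids)
  is_snv <- nchar(muts$ref) == 1L & nchar(muts$alt) == 1L &
    muts$ref %in% c("A", "C", "G", "T") & muts$alt %in% c("A", "C", "G", "T")
  ns_classes <- c("MISSENSE", "STOPGAIN", "STOPLOSS")
  ns <- sum(is_snv & muts$consequence %in% ns_classes)
  if (include_splice_in_ns) {
    ns <- ns + sum(muts$consequence == "SPLICE_SITE")
  }
  if (include_indels_in_ns) {
    ns <- ns + sum(muts$consequence %in%
                     c("FRAMESHIFT_INS", "FRAMESHIFT_DEL",
                       "NONFRAMESHIFT_INDEL"))
  }
  s <- sum(is_snv & muts$consequence == "SYNONYMOUS")
  c(ns = as.integer(ns), s = as.integer(s))
}

#' Mutation ids present in given stages (post-rescue)
#'
#' Convenience selectors for building the groups the selection test is run
#' on: all mutations of a patient's primary tumor, or mutations specific to
#' one metastatic stage (present there and in no other tumor stage).
#'
#' @param filter_result result of [apply_filters()].
#' @param stages stage(s) of interest.
#' @param specific if TRUE, require absence from all other tumor stages.
#' @return character vector of mutation ids.
#' @export
mutations_in_stage <- function(filter_result, stages, specific = FALSE) {
  pres <- filter_result$presence %>%
    filter(.data$present) %>%
    group_by(.data$mut_id) %>%
    summarise(in_stage = any(.data$stage %in% stages),
              elsewhere = any(!.data$stage %in% stages), .groups = "drop")
  hit <- pres$in_stage & (!specific | !pres$elsewhere)
  pres$mut_id[hit]
}

#' One-tailed binomial selection test on NS and S counts
#'
#' Tests whether the observed non-synonymous fraction exceeds the neutral
#' expectation `null_ratio : 1` (default 2:1, i.e. p0 = 2/3), and estimates
#' the number of driver mutations as the non-synonymous excess over that
#' expectation, `max(NS - round(null_ratio * S), 0)`.
#'
#' @param ns non-synonymous count.
#' @param s synonymous count; `ns + s` must be at least 1.
#' @param null_ratio neutral NS:S ratio (default 2).
#' @param label optional group label carried into the result.
#' @return a one-row result tibble: `label`, `ns`, `s`, `ratio` (NA when
#'   `s = 0`), `p_value`, `driver_estimate`.
#' @export
#' @examples
#' selection_test(177, 47)   # ratio 3.76..., p ~ 3e-5, 83 estimated drivers
selection_test <- function(ns, s, null_ratio = 2, label = NA_character_) {
  ns <- as.integer(ns); s <- as.integer(s)
  if (ns + s < 1L) abort("selection test needs at least one mutation")
  p0 <- null_ratio / (null_ratio + 1)
  new_result_tbl(tibble(
    label = label,
    ns = ns, s = s,
    ratio = if (s > 0) ns / s else NA_real_,
    p_value = binom_tail_exact(ns, ns + s, p0),
    driver_estimate = max(ns - as.integer(round(null_ratio * s)), 0L)),
    "selection_test")
}

#' Selection tests over a set of mutation groups
#'
#' @param cohort a [variant_cohort()].
#' @param groups named list of mutation-id vectors (one test per group).
#' @param null_ratio neutral NS:S ratio.
#' @param ... passed to [count_classes()].
#' @return result tibble with one row per group.
#' @export
selection_test_groups <- function(cohort, groups, null_ratio = 2, ...) {
  rows <- lapply(names(groups), function(lbl) {
    cnt <- count_classes(cohort, groups[[lbl]], ...)
    selection_test(cnt[["ns"]], cnt[["s"]], null_ratio, label = lbl)
  })
  new_result_tbl(bind_rows(rows), "selection_test")
}

#' Truncate to two decimals for display
#'
#' Printed NS:S ratios follow a truncation convention (177/47 = 3.7659
#' displays as 3.76); full precision is kept in the result tables and only
#' display uses this helper.
#'
#' @param x numeric vector.
#' @param digits decimal places kept.
#' @return truncated numeric vector.
#' @export
trunc_decimals <- function(x, digits = 2L) {
  trunc(x * 10^digits) / 10^digits
}
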