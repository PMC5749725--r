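# The validation criteria: clean normal (< 0.02), depth >= 50 everywhere,
# >= 0.05 BAF in some tumor, rescue at >= 0.025 when depth > 200.

two_tumor <- function(n_a, t1_d, t1_a, t2_d, t2_a, n_d = 60, ...) {
  one_patient(STG2, tibble::tibble(
    pos = 100, N_d = n_d, N_a = n_a,
    T1_d = t1_d, T1_a = t1_a, T2_d = t2_d, T2_a = t2_a, ...))
}

test_that("retention rules and the rescue rule follow the stated thresholds", {
  # clean case: signal in tumor 1 only
  fr <- apply_filters(two_tumor(0, 60, 6, 60, 0))
  expect_retained(fr, fr$decisions$mut_id)
  expect_equal(unname(presence_of(fr, fr$decisions$mut_id)), c(TRUE, FALSE))

  # rescue: BAF 0.028 at depth 250 counts as present in the second tumor
  fr <- apply_filters(two_tumor(0, 60, 6, 250, 7))
  expect_equal(unname(presence_of(fr, fr$decisions$mut_id)), c(TRUE, TRUE))

  # same BAF at depth 150: rescue depth not exceeded
  fr <- apply_filters(two_tumor(0, 60, 6, 150, 5))   # BAF 0.033
  expect_equal(unname(presence_of(fr, fr$decisions$mut_id)), c(TRUE, FALSE))

  # rescue depth bound is strict: exactly 200 does not qualify
  fr <- apply_filters(two_tumor(0, 60, 6, 200, 6))   # BAF 0.03
  expect_equal(unname(presence_of(fr, fr$decisions$mut_id)), c(TRUE, FALSE))
  fr <- apply_filters(two_tumor(0, 60, 6, 201, 7))   # BAF 0.0348, depth > 200
  expect_equal(unname(presence_of(fr, fr$decisions$mut_id)), c(TRUE, TRUE))
})

test_that("boundary semantics: normal BAF exclusive, depth and tumor BAF inclusive", {
  # normal BAF 0.025 >= 0.02 -> contamination
  fr <- apply_filters(two_tumor(n_a = 2, 60, 6, 60, 0, n_d = 80))
  expect_equal(reasons_of(fr, fr$decisions$mut_id), "NORMAL_CONTAMINATION")

  # normal BAF exactly at the bound is rejected; just below passes
  fr <- apply_filters(two_tumor(n_a = 2, 60, 6, 60, 0, n_d = 100))  # 0.02
  expect_equal(fr$decisions$verdict, "REJECTED")
  fr <- apply_filters(two_tumor(n_a = 1, 60, 6, 60, 0, n_d = 100))  # 0.01
  expect_equal(fr$decisions$verdict, "RETAINED")

  # depth 50 in every sample is enough; 49 anywhere is not
  fr <- apply_filters(two_tumor(0, 50, 3, 50, 0, n_d = 50))  # BAF 0.06
  expect_equal(fr$decisions$verdict, "RETAINED")
  fr <- apply_filters(two_tumor(0, 49, 3, 50, 0, n_d = 50))
  expect_equal(reasons_of(fr, fr$decisions$mut_id), "LOW_DEPTH")

  # tumor BAF exactly 0.05 qualifies; 0.049 does not
  fr <- apply_filters(two_tumor(0, 100, 5, 60, 0))
  expect_equal(fr$decisions$verdict, "RETAINED")
  fr <- apply_filters(two_tumor(0, 1000, 49, 60, 0))
  expect_equal(reasons_of(fr, fr$decisions$mut_id), "NO_TUMOR_SIGNAL")
})

test_that("region class, population SNPs, blacklist and flags reject with ordered reasons", {
  co <- one_patient(STG2, tibble::tibble(
    pos = c(100, 200, 300, 400),
    region_class = c("INTRONIC", "EXONIC", "EXONIC", "EXONIC"),
    pop_af = c(NA, 0.02, NA, 0.01),
    flags = c(NA, NA, "REPEAT_REGION", "ADJACENT_CLUSTER"),
    N_d = 60, N_a = 0, T1_d = 60, T1_a = 6, T2_d = 60, T2_a = 0))
  fr <- apply_filters(co)
  ids <- sort(fr$decisions$mut_id)   # order: pos 100, 200, 300, 400
  expect_equal(reasons_of(fr, ids[1]), "REGION_EXCLUDED")
  expect_equal(reasons_of(fr, ids[2]), "POPULATION_SNP")
  expect_equal(reasons_of(fr, ids[3]), "BLACKLISTED")
  expect_equal(reasons_of(fr, ids[4]), "CLUSTERED")

  # pop_af exactly 0.01 is not "> 1%": no SNP reason on the fourth mutation
  expect_false("POPULATION_SNP" %in% reasons_of(fr, ids[4]))

  # interval blacklist
  bl <- tibble::tibble(chrom = "1", start = 90L, end = 110L)
  fr_bl <- apply_filters(co, blacklist = bl)
  expect_true("BLACKLISTED" %in% reasons_of(fr_bl, ids[1]))

  # several violations accumulate in evaluation order
  co2 <- one_patient(STG2, tibble::tibble(
    pos = 100, region_class = "INTRONIC", pop_af = 0.5,
    N_d = 60, N_a = 30, T1_d = 60, T1_a = 30, T2_d = 60, T2_a = 0))
  fr2 <- apply_filters(co2)
  expect_equal(reasons_of(fr2, fr2$decisions$mut_id),
               c("NORMAL_CONTAMINATION", "REGION_EXCLUDED", "POPULATION_SNP"))
})

test_that("a mutation without a normal observation is an error", {
  co <- one_patient(STG2, tibble::tibble(
    pos = 100, N_d = 60, N_a = 0, T1_d = 60, T1_a = 6, T2_d = 60, T2_a = 0))
  co$observations <- co$observations[
    !grepl("^N$", co$observations$sample_id), ]
  expect_error(apply_filters(co), "normal observation")
})

test_that("adjacent-variant clusters are flagged within the window", {
  co <- one_patient(c(T1 = "PRIMARY"), tibble::tibble(
    pos = c(100, 105, 108), N_d = 60, N_a = 0, T1_d = 60, T1_a = 6))
  flagged <- flag_clusters(co, window = 10, count = 3)
  expect_true(all(vapply(flagged$mutations$flags,
                         function(f) "ADJACENT_CLUSTER" %in% f, logical(1))))

  far <- one_patient(c(T1 = "PRIMARY"), tibble::tibble(
    pos = c(100, 1100), N_d = 60, N_a = 0, T1_d = 60, T1_a = 6))
  flagged2 <- flag_clusters(far, window = 10, count = 3)
  expect_false(any(vapply(flagged2$mutations$flags,
                          function(f) "ADJACENT_CLUSTER" %in% f, logical(1))))

  empty <- subset_cohort(far, character(0))
  expect_identical(flag_clusters(empty), empty)
})

test_that("retention is monotone in depth and BAF thresholds", {
  sim <- simulate_cohort(cohort_sim_config(seed = 42, n_patients = 3,
                                           n_truncal = 40, n_private = 10,
                                           mean_depth = 120,
                                           depth_dispersion = 3,
                                           purity = 0.25,
                                           pop_snp_rate = 0.05))
  retained_ids <- function(cfg) {
    d <- apply_filters(sim$cohort, cfg)$decisions
    d$mut_id[d$verdict == "RETAINED"]
  }
  base <- retained_ids(filter_config())
  stricter_baf <- retained_ids(filter_config(tumor_baf_min = 0.15,
                                             rescue_baf_min = 0.02))
  stricter_depth <- retained_ids(filter_config(min_depth_all = 100))
  laxer <- retained_ids(filter_config(min_depth_all = 10,
                                      tumor_baf_min = 0.02,
                                      rescue_baf_min = 0.02))
  expect_true(all(stricter_baf %in% base))
  expect_true(all(stricter_depth %in% base))
  expect_true(all(base %in% laxer))
})

test_that("degenerate thresholds pass every unflagged mutation through", {
  sim <- simulate_cohort(cohort_sim_config(seed = 5, n_patients = 2,
                                           n_truncal = 30, n_private = 5,
                                           purity = 0.1, pop_snp_rate = 0.1,
                                           blacklist_rate = 0.1))
  cfg <- filter_config(normal_baf_max = 1, min_depth_all = 0,
                       tumor_baf_min = 0, rescue_baf_min = 0,
                       pop_af_max = 1, allowed_regions = REGION_CLASSES)
  fr <- apply_filters(sim$cohort, cfg)
  flagged <- vapply(sim$cohort$mutations$flags, length, integer(1)) > 0
  expect_setequal(fr$decisions$mut_id[fr$decisions$verdict == "RETAINED"],
                  sim$cohort$mutations$mut_id[!flagged])
})

test_that("verdicts are independent of mutation order", {
  sim <- simulate_cohort(cohort_sim_config(seed = 9, n_patients = 2,
                                           n_truncal = 25, n_private = 5,
                                           pop_snp_rate = 0.1))
  co <- sim$cohort
  fr1 <- apply_filters(co)
  perm <- sample(nrow(co$mutations))
  co2 <- variant_cohort(co$samples, co$mutations[perm, ],
                        co$observations[sample(nrow(co$observations)), ])
  fr2 <- apply_filters(co2)
  d1 <- dplyr::arrange(fr1$decisions, mut_id)
  d2 <- dplyr::arrange(fr2$decisions, mut_id)
  expect_identical(d1$verdict, d2$verdict)
  expect_identical(d1$reasons, d2$reasons)
})

test_that("filter configs read back from key=value files", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# validation thresholds", "normal_baf_max = 0.03",
               "min_depth_all = 30", "allowed_regions = EXONIC,SPLICING"),
             path)
  cfg <- read_filter_config(path)
  expect_equal(cfg$normal_baf_max, 0.03)
  expect_equal(cfg$min_depth_all, 30L)
  expect_equal(cfg$allowed_regions, c("EXONIC", "SPLICING"))
  writeLines("nonsense = 1", path)
  expect_error(read_filter_config(path), "unknown filter config key")
})
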