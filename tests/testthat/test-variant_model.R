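write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

header <- paste0("#", paste(c("patient", "sample", "stage", "chrom", "pos",
                              "ref", "alt", "depth", "alt_reads",
                              "region_class", "consequence"),
                            collapse = "\t"))

row_line <- function(sample, stage, depth, alt_reads, pos = 100) {
  paste("P1", sample, stage, "1", pos, "A", "G", depth, alt_reads,
        "EXONIC", "MISSENSE", sep = "\t")
}

test_that("rows sharing a mutation key merge into one record, invariant to row order", {
  rows <- c(row_line("N", "NORMAL", 60, 0),
            row_line("T1", "PRIMARY", 80, 20),
            row_line("T2", "DISTANT_MET", 70, 15))
  co <- read_variant_table(write_tsv_lines(c(header, rows)))
  expect_equal(n_mutations(co), 1L)
  expect_equal(nrow(co$observations), 3L)
  expect_equal(sort(co$samples$stage), sort(c("NORMAL", "PRIMARY",
                                              "DISTANT_MET")))

  shuffled <- read_variant_table(write_tsv_lines(c(header, rows[c(3, 1, 2)])))
  expect_identical(co, shuffled)
})

test_that("schema and invariant violations are reported with context", {
  no_depth <- sub("\tdepth", "", header, fixed = TRUE)
  expect_error(read_variant_table(write_tsv_lines(no_depth)), "depth")

  bad <- write_tsv_lines(c(header, row_line("N", "NORMAL", 10, 12)))
  expect_error(read_variant_table(bad), "alt_reads > depth.*1")

  expect_error(read_variant_table(tempfile()), "no such file")
})

test_that("an empty table yields an empty cohort without error", {
  co <- read_variant_table(write_tsv_lines(header))
  expect_equal(n_mutations(co), 0L)
  expect_s3_class(co, "variant_cohort")
})

test_that("cohort validation enforces sample topology and coordinates", {
  samples <- tibble::tibble(patient_id = "P1", sample_id = c("N", "T"),
                            stage = c("NORMAL", "PRIMARY"))
  mut <- tibble::tibble(patient_id = "P1", mut_id = "P1:1:5:A:G",
                        gene = "G1", chrom = "1", pos = 5L, ref = "A",
                        alt = "G", region_class = "EXONIC",
                        consequence = "MISSENSE", pop_af = NA_real_)
  obs <- tibble::tibble(mut_id = "P1:1:5:A:G", sample_id = c("N", "T"),
                        depth = c(50L, 50L), alt_reads = c(0L, 10L))
  expect_s3_class(variant_cohort(samples, mut, obs), "variant_cohort")

  expect_error(variant_cohort(samples[samples$stage != "NORMAL", ], mut, obs),
               "NORMAL")
  mut_bad <- mut; mut_bad$pos <- 0L
  mut_bad$mut_id <- "P1:1:0:A:G"
  expect_error(variant_cohort(samples, mut_bad, obs), "1-based")
  obs_bad <- obs; obs_bad$sample_id[2] <- "ELSEWHERE"
  expect_error(variant_cohort(samples, mut, obs_bad), "sample")
})

test_that("BAF is alt/depth and undefined at zero depth", {
  expect_equal(baf(c(5, 0), c(100, 10)), c(0.05, 0))
  expect_error(baf(0, 0), "depth 0")
  expect_error(baf(12, 10), "exceeds depth")
})

test_that("GMT parsing: one set per line, deduplicated, with overridable family size", {
  path <- write_tsv_lines(c("setA\tdesc\tTP53\tBRCA2\ttp53",
                            "setB\tdesc\tRUNX1"))
  gs <- read_gmt(path)
  expect_equal(length(gs$sets), 2L)
  expect_equal(gs$collection_size, 2L)
  expect_equal(gs$sets$setA, c("TP53", "BRCA2"))

  gs186 <- read_gmt(path, collection_size = 186)
  expect_equal(gs186$collection_size, 186L)
  expect_error(read_gmt(path, collection_size = 1), "smaller")

  bad <- write_tsv_lines(c("setA\tdesc\tTP53", "justname"))
  expect_error(read_gmt(bad), "line 2")
})

test_that("variant tables round-trip through write and read", {
  sim <- simulate_cohort(cohort_sim_config(seed = 11, n_patients = 2,
                                           n_truncal = 10, n_private = 3,
                                           pop_snp_rate = 0.2,
                                           blacklist_rate = 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(sim$cohort, path)
  back <- read_variant_table(path)
  expect_identical(dplyr::arrange(sim$cohort$samples, sample_id),
                   dplyr::arrange(back$samples, sample_id))
  expect_identical(sim$cohort$mutations, back$mutations)
  expect_identical(sim$cohort$observations, back$observations)
})

test_that("result tables round-trip through TSV and JSON", {
  res <- selection_test(177, 47, label = "PT4")
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_results(res, path, format = fmt)
    back <- read_results(path, format = fmt)
    expect_equal(as.data.frame(back), as.data.frame(res))
    expect_equal(attr(back, "result_type"), "selection_test")
  }

  enr <- enrich(c("TP53", "BRCA2"),
                gene_set_collection("toy", list(s1 = c("TP53", "MDM2"))),
                N = 1000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(enr, path)
  expect_equal(as.data.frame(read_results(path)), as.data.frame(enr))

  expect_error(write_results(tibble::tibble(x = 1), tempfile()),
               "not a pipeline result")
})

test_that("BED blacklists convert from 0-based half-open to 1-based closed", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr2\t0\t5"), path)
  bl <- read_bed_blacklist(path)
  expect_equal(bl$start, c(11L, 1L))
  expect_equal(bl$end, c(20L, 5L))
})

test_that("VCF ingestion maps FORMAT depth and allelic depths per sample", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNORM\tTUM",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD\t0/0:60:60,0\t0/1:80:60,20",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP:AD\t0/0:55:55,0\t0/1:90:72,18"),
    path)
  co <- read_vcf_cohort(path, "P1",
                        c(NORM = "NORMAL", TUM = "PRIMARY"))
  expect_equal(n_mutations(co), 2L)
  tum <- co$observations[co$observations$sample_id == "TUM", ]
  expect_equal(sort(tum$alt_reads), c(18L, 20L))
  expect_equal(sort(tum$depth), c(80L, 90L))
})
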