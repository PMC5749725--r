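#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate select arrange group_by ungroup summarise
#'   distinct left_join inner_join anti_join bind_rows n n_distinct first across
#'   all_of row_number if_else rename count pull
#' @importFrom stats pbinom phyper rbinom rnbinom runif setNames
#' @importFrom utils head read.delim write.table
NULL

# ---- controlled vocabularies ------------------------------------------------

#' Controlled vocabularies for the cohort model
#'
#' Tumor sampling stages, Annovar-style region classes, consequence classes
#' and curation flags used throughout the pipeline. Every normal sample is
#' stage `NORMAL`; tumor stages follow the successive steps of progression:
#' pre-invasive DCIS, primary tumor, axillary lymph-node metastasis and
#' asynchronous distant metastasis.
#'
#' @name vocab
NULL

#' @rdname vocab
#' @export
STAGES <- c("NORMAL", "DCIS", "PRIMARY", "ALN_MET", "DISTANT_MET")

#' @rdname vocab
#' @export
TUMOR_STAGES <- c("DCIS", "PRIMARY", "ALN_MET", "DISTANT_MET")

#' @rdname vocab
#' @export
MET_STAGES <- c("ALN_MET", "DISTANT_MET")

#' @rdname vocab
#' @export
REGION_CLASSES <- c("EXONIC", "SPLICING", "INTRONIC", "INTERGENIC",
                    "DOWNSTREAM", "NCRNA_INTRONIC", "OTHER")

#' @rdname vocab
#' @export
CONSEQUENCES <- c("SYNONYMOUS", "MISSENSE", "STOPGAIN", "STOPLOSS",
                  "FRAMESHIFT_INS", "FRAMESHIFT_DEL", "NONFRAMESHIFT_INDEL",
                  "SPLICE_SITE", "OTHER")

#' @rdname vocab
#' @export
CURATION_FLAGS <- c("REPEAT_REGION", "ADJACENT_CLUSTER", "ERROR_PRONE_REGION")

# Consequence classes regarded as protein-altering for category/recurrence
# analyses ("non-synonymous and splice site mutations" in the tables).
#' @rdname vocab
#' @export
PROTEIN_ALTERING <- c("MISSENSE", "STOPGAIN", "STOPLOSS", "FRAMESHIFT_INS",
                      "FRAMESHIFT_DEL", "NONFRAMESHIFT_INDEL", "SPLICE_SITE")

# ---- B-allele frequency -----------------------------------------------------

#' B-allele frequency of a sequencing observation
#'
#' The fraction of reads supporting the alternate allele, `alt_reads / depth`.
#' Undefined at zero depth: requesting it there is an error because a site
#' with no coverage carries no allele-fraction information.
#'
#' @param alt_reads integer vector of alternate-allele read counts.
#' @param depth integer vector of total read depths.
#' @return numeric vector of allele fractions in `[0, 1]`.
#' @export
#' @examples
#' baf(5, 100)
baf <- function(alt_reads, depth) {
  if (any(depth == 0)) {
    abort("BAF is undefined at depth 0")
  }
  if (any(alt_reads > depth)) {
    abort("alt_reads exceeds depth")
  }
  alt_reads / depth
}

# BAF that tolerates zero depth (returns NA); internal use in filters where a
# zero-depth sample already fails the depth criterion.
baf_or_na <- function(alt_reads, depth) {
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

# ---- cohort container -------------------------------------------------------

mutation_key <- function(patient_id, chrom, pos, ref, alt) {
  paste(patient_id, chrom, pos, ref, alt, sep = ":")
}

#' Construct a multi-sample somatic variant cohort
#'
#' The central container for the pipeline: per-patient sample topology plus
#' somatic mutations, each carrying one sequencing observation (depth,
#' alt-read count) per sample of its patient.
#'
#' @param samples tibble with columns `patient_id`, `sample_id`, `stage`
#'   (one of [STAGES]); exactly one `NORMAL` sample per patient.
#' @param mutations tibble with columns `patient_id`, `mut_id`, `gene`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `region_class`, `consequence`,
#'   `cdna_change`, `aa_change`, `pop_af` (population allele frequency,
#'   `NA` if unobserved), `flags` (list column of curation flags).
#' @param observations tibble with columns `mut_id`, `sample_id`, `depth`,
#'   `alt_reads`; exactly one row per mutation x sample.
#' @return an object of class `variant_cohort`.
#' @export
variant_cohort <- function(samples, mutations, observations) {
  samples <- as_tibble(samples)
  mutations <- as_tibble(mutations)
  observations <- as_tibble(observations)

  stopifnot(all(c("patient_id", "sample_id", "stage") %in% names(samples)))
  bad_stage <- setdiff(unique(samples$stage), STAGES)
  if (length(bad_stage)) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  n_normal <- samples %>%
    group_by(.data$patient_id) %>%
    summarise(k = sum(.data$stage == "NORMAL"), .groups = "drop")
  if (nrow(n_normal) && any(n_normal$k != 1)) {
    abort("each patient must have exactly one NORMAL sample")
  }

  needed <- c("patient_id", "mut_id", "gene", "chrom", "pos", "ref", "alt",
              "region_class", "consequence", "pop_af")
  missing_cols <- setdiff(needed, names(mutations))
  if (length(missing_cols)) {
    abort(paste0("mutations table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"cdna_change" %in% names(mutations)) mutations$cdna_change <- NA_character_
  if (!"aa_change" %in% names(mutations)) mutations$aa_change <- NA_character_
  if (!"flags" %in% names(mutations)) {
    mutations$flags <- replicate(nrow(mutations), character(0), simplify = FALSE)
  }
  if (nrow(mutations)) {
    if (any(mutations$pos < 1)) abort("positions are 1-based; pos must be >= 1")
    if (anyDuplicated(mutations$mut_id)) {
      abort("duplicate mutation key within a patient")
    }
    bad_cons <- setdiff(unique(mutations$consequence), CONSEQUENCES)
    if (length(bad_cons)) {
      abort(paste0("unknown consequence class(es): ",
                   paste(bad_cons, collapse = ", ")))
    }
    bad_region <- setdiff(unique(mutations$region_class), REGION_CLASSES)
    if (length(bad_region)) {
      abort(paste0("unknown region class(es): ",
                   paste(bad_region, collapse = ", ")))
    }
  }

  if (nrow(observations)) {
    if (any(observations$alt_reads > observations$depth)) {
      abort("alt_reads exceeds depth in observations")
    }
    if (any(observations$depth < 0) || any(observations$alt_reads < 0)) {
      abort("read counts must be non-negative")
    }
    dup <- observations %>% count(.data$mut_id, .data$sample_id) %>%
      filter(.data$n > 1)
    if (nrow(dup)) {
      abort("more than one observation for the same mutation and sample")
    }
    known_samples <- mutations %>%
      select("mut_id", "patient_id") %>%
      inner_join(samples, by = "patient_id", relationship = "many-to-many")
    orphan <- observations %>%
      anti_join(known_samples, by = c("mut_id", "sample_id"))
    if (nrow(orphan)) {
      abort("observation refers to a sample outside its patient's sample list")
    }
  }

  # canonical form: fixed column order/types, rows sorted -> cohorts built
  # from the same content compare identical regardless of input order
  mutations <- mutations[, c("patient_id", "mut_id", "gene", "chrom", "pos",
                             "ref", "alt", "region_class", "consequence",
                             "cdna_change", "aa_change", "pop_af", "flags")]
  for (col in c("gene", "chrom", "ref", "alt")) {
    mutations[[col]] <- unname(mutations[[col]])
  }
  mutations$pos <- as.integer(mutations$pos)
  observations$depth <- as.integer(observations$depth)
  observations$alt_reads <- as.integer(observations$alt_reads)
  structure(
    list(samples = arrange(samples, .data$patient_id, .data$sample_id),
         mutations = arrange(mutations, .data$patient_id, .data$chrom,
                             .data$pos, .data$ref, .data$alt),
         observations = arrange(observations, .data$mut_id, .data$sample_id)),
    class = "variant_cohort"
  )
}

#' @export
print.variant_cohort <- function(x, ...) {
  cat("<variant_cohort> ",
      n_distinct(x$samples$patient_id), " patient(s), ",
      nrow(x$samples), " sample(s), ",
      nrow(x$mutations), " mutation(s)\n", sep = "")
  invisible(x)
}

#' Number of mutations in a cohort
#' @param cohort a `variant_cohort`.
#' @return integer count of distinct mutations.
#' @export
n_mutations <- function(cohort) nrow(cohort$mutations)

#' Restrict a cohort to a subset of mutations
#'
#' @param cohort a `variant_cohort`.
#' @param mut_ids character vector of mutation keys to keep.
#' @return a `variant_cohort` containing only those mutations (sample
#'   topology unchanged).
#' @export
subset_cohort <- function(cohort, mut_ids) {
  variant_cohort(
    cohort$samples,
    filter(cohort$mutations, .data$mut_id %in% mut_ids),
    filter(cohort$observations, .data$mut_id %in% mut_ids)
  )
}

# Long observation view with stage and BAF attached; workhorse for filters
# and categorisation.
obs_with_stage <- function(cohort) {
  cohort$observations %>%
    left_join(select(cohort$mutations, "mut_id", "patient_id"), by = "mut_id") %>%
    left_join(cohort$samples, by = c("patient_id", "sample_id")) %>%
    mutate(baf = baf_or_na(.data$alt_reads, .data$depth))
}

# ---- variant table I/O ------------------------------------------------------

VARIANT_TABLE_COLS <- c("patient", "sample", "stage", "chrom", "pos", "ref",
                        "alt", "depth", "alt_reads", "region_class",
                        "consequence")
VARIANT_TABLE_OPT <- c("gene", "cdna_change", "aa_change", "pop_af", "flags")

#' Read an annotated multi-sample variant table
#'
#' The canonical interchange format: one tab-separated row per mutation x
#' sample observation, `#`-prefixed header line. Rows sharing a
#' (patient, chrom, pos, ref, alt) key are merged into a single mutation
#' record with one observation per sample, so the cohort is invariant to
#' row order.
#'
#' Mandatory columns: `patient`, `sample`, `stage`, `chrom`, `pos`, `ref`,
#' `alt`, `depth`, `alt_reads`, `region_class`, `consequence`. Optional:
#' `gene`, `cdna_change`, `aa_change`, `pop_af`, `flags`
#' (comma-separated curation flags).
#'
#' @param path path to the TSV file.
#' @return a [variant_cohort()].
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    return(variant_cohort(empty_samples(), empty_mutations(), empty_observations()))
  }
  header <- sub("^#", "", first)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(VARIANT_TABLE_COLS, cols)
  if (length(missing_cols)) {
    abort(paste0("variant table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- read.delim(path, header = FALSE, skip = 1L, col.names = cols,
                    sep = "\t", colClasses = "character",
                    na.strings = c("NA", "."), quote = "")
  if (!nrow(raw)) {
    return(variant_cohort(empty_samples(), empty_mutations(), empty_observations()))
  }
  raw <- as_tibble(raw) %>%
    mutate(pos = as.integer(.data$pos),
           depth = as.integer(.data$depth),
           alt_reads = as.integer(.data$alt_reads))
  if ("pop_af" %in% names(raw)) raw$pop_af <- as.numeric(raw$pop_af)

  bad <- which(raw$alt_reads > raw$depth)
  if (length(bad)) {
    abort(paste0("alt_reads > depth at data row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }

  cohort_from_long(raw)
}

# Assemble a variant_cohort from the long (one row per observation) layout.
cohort_from_long <- function(raw) {
  for (col in VARIANT_TABLE_OPT) {
    if (!col %in% names(raw)) {
      raw[[col]] <- if (col == "pop_af") NA_real_ else NA_character_
    }
  }
  samples <- raw %>%
    distinct(patient_id = .data$patient, sample_id = .data$sample,
             stage = .data$stage)
  raw$mut_id <- mutation_key(raw$patient, raw$chrom, raw$pos, raw$ref, raw$alt)
  mutations <- raw %>%
    group_by(.data$mut_id) %>%
    summarise(patient_id = first(.data$patient),
              gene = first(.data$gene),
              chrom = first(.data$chrom), pos = first(.data$pos),
              ref = first(.data$ref), alt = first(.data$alt),
              region_class = first(.data$region_class),
              consequence = first(.data$consequence),
              cdna_change = first(.data$cdna_change),
              aa_change = first(.data$aa_change),
              pop_af = first(.data$pop_af),
              flags = list(parse_flags(first(.data$flags))),
              .groups = "drop")
  observations <- raw %>%
    select("mut_id", sample_id = "sample", "depth", "alt_reads")
  variant_cohort(samples, mutations, observations)
}

parse_flags <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  sort(strsplit(x, ",", fixed = TRUE)[[1]])
}

empty_samples <- function() {
  tibble(patient_id = character(), sample_id = character(), stage = character())
}
empty_mutations <- function() {
  tibble(patient_id = character(), mut_id = character(), gene = character(),
         chrom = character(), pos = integer(), ref = character(),
         alt = character(), region_class = character(),
         consequence = character(), cdna_change = character(),
         aa_change = character(), pop_af = numeric(), flags = list())
}
empty_observations <- function() {
  tibble(mut_id = character(), sample_id = character(), depth = integer(),
         alt_reads = integer())
}

#' Write a cohort back to the annotated variant-table format
#'
#' Inverse of [read_variant_table()]: `read_variant_table(write_variant_table(x))`
#' reconstructs an identical cohort.
#'
#' @param cohort a [variant_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(cohort, path) {
  long <- cohort$observations %>%
    left_join(cohort$mutations, by = "mut_id") %>%
    left_join(cohort$samples, by = c("patient_id", "sample_id")) %>%
    mutate(flags = vapply(.data$flags, paste, "", collapse = ","),
           pop_af = fmt_full(.data$pop_af)) %>%
    select(patient = "patient_id", sample = "sample_id", "stage", "chrom",
           "pos", "ref", "alt", "depth", "alt_reads", "region_class",
           "consequence", "gene", "cdna_change", "aa_change", "pop_af",
           "flags") %>%
    arrange(.data$patient, .data$chrom, .data$pos, .data$ref, .data$alt,
            .data$sample)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(long), collapse = "\t")), con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Read a gene-set collection from a GMT file
#'
#' One set per line: set name, description, then member gene symbols, all
#' tab-separated. Symbols are uppercased; duplicates within a set are
#' dropped. `collection_size` is the number of tests the collection
#' represents for FDR purposes; it defaults to the number of lines but can
#' be overridden when the file holds only a displayed subset of a larger
#' tested collection (e.g. the 186 KEGG sets behind a five-row table).
#'
#' @param path path to the GMT file.
#' @param collection_size optional integer overriding the number of sets
#'   counted in multiple-testing correction; must be at least the number of
#'   stored sets.
#' @return an object of class `gene_set_collection`: list with `name`,
#'   `sets` (named list of character vectors) and `collection_size`.
#' @export
read_gmt <- function(path, collection_size = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(paste0("malformed GMT line (need >= 3 fields) at line ",
                 short[1]))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(name = basename(path), sets = sets,
                      collection_size = collection_size)
}

#' @rdname read_gmt
#' @param name label for the collection.
#' @param sets named list of character vectors of gene symbols.
#' @export
gene_set_collection <- function(name, sets, collection_size = NULL) {
  if (is.null(collection_size)) collection_size <- length(sets)
  if (collection_size < length(sets)) {
    abort("collection_size cannot be smaller than the number of stored sets")
  }
  sets <- lapply(sets, function(s) unique(toupper(s)))
  structure(list(name = name, sets = sets,
                 collection_size = as.integer(collection_size)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> '", x$name, "': ", length(x$sets),
      " stored set(s), collection size m = ", x$collection_size, "\n", sep = "")
  invisible(x)
}

#' Read a plain-text gene list (one symbol per line)
#' @param path path to the file.
#' @return character vector of uppercased gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  unique(toupper(x[nzchar(x)]))
}

# ---- BED blacklist ----------------------------------------------------------

#' Read a curation blacklist from a BED file
#'
#' BED intervals are 0-based, half-open; they are converted to the 1-based,
#' fully closed convention used by the cohort (a BED record `chr1 10 20`
#' covers 1-based positions 11..20). The parsing is delegated to
#' `rtracklayer::import`.
#'
#' @param path path to the BED file.
#' @return tibble with columns `chrom`, `start`, `end` (1-based closed).
#' @export
read_bed_blacklist <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading BED blacklists requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

# ---- VCF ingestion ----------------------------------------------------------

#' Ingest raw calls from a VCF file into the cohort model
#'
#' A thin mapping path for callers that emit multi-sample VCFs. Depth and
#' alt-read counts are taken from per-sample FORMAT fields (by default `DP`
#' and the second element of `AD`). Annotation columns the VCF cannot supply
#' (consequence class, region class) default to `OTHER`/`EXONIC` and are
#' expected to be overwritten by the caller's own annotation step; this
#' reader exists so raw calls can enter the validated container, not to
#' re-implement annotation.
#'
#' @param path path to a VCF 4.x file.
#' @param patient_id patient the samples belong to.
#' @param sample_stages named character vector mapping VCF sample names to
#'   stages in [STAGES]; must include exactly one `NORMAL`.
#' @param dp_field,ad_field FORMAT field names for depth and allelic depths.
#' @return a [variant_cohort()].
#' @export
read_vcf_cohort <- function(path, patient_id, sample_stages,
                            dp_field = "DP", ad_field = "AD") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF ingestion requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, element = dp_field, as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = ad_field)
  vcf_samples <- colnames(dp)
  unknown <- setdiff(names(sample_stages), vcf_samples)
  if (length(unknown)) {
    abort(paste0("sample(s) not in VCF: ", paste(unknown, collapse = ", ")))
  }
  use <- names(sample_stages)
  alt_from_ad <- function(x) {
    as.integer(vapply(strsplit(x, ",", fixed = TRUE),
                      function(p) if (length(p) >= 2) p[2] else NA_character_, ""))
  }
  rows <- lapply(use, function(smp) {
    tibble(patient = patient_id, sample = smp,
           stage = unname(sample_stages[smp]),
           chrom = fix$CHROM, pos = as.integer(fix$POS),
           ref = fix$REF, alt = fix$ALT,
           depth = as.integer(dp[, smp]),
           alt_reads = alt_from_ad(ad[, smp]),
           region_class = "EXONIC", consequence = "OTHER")
  })
  long <- bind_rows(rows) %>%
    filter(!is.na(.data$depth), !is.na(.data$alt_reads))
  cohort_from_long(long)
}

# ---- result I/O -------------------------------------------------------------

RESULT_TYPES <- c("selection_test", "enrichment", "category_assignment",
                  "recurrence_within", "recurrence_across", "driver_call",
                  "filter_decision")

new_result_tbl <- function(x, type) {
  stopifnot(type %in% RESULT_TYPES)
  x <- as_tibble(x)
  class(x) <- c(paste0("mutsteps_", type), "mutsteps_result", class(x))
  attr(x, "result_type") <- type
  x
}

#' Write a pipeline result table to disk
#'
#' Results round-trip losslessly: `read_results(write_results(x, p))` equals
#' `x`. TSV output carries the result type in a `#`-comment line so the
#' reader can restore the class; JSON embeds it in the payload.
#'
#' @param x a result table produced by the pipeline (class `mutsteps_result`).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  type <- attr(x, "result_type")
  if (is.null(type)) abort("not a pipeline result table")
  plain <- as.data.frame(x)
  if (format == "tsv") {
    for (col in names(plain)) {
      if (is.double(plain[[col]])) plain[[col]] <- fmt_full(plain[[col]])
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# mutsteps_result: ", type), con)
    writeLines(paste0("#", paste(names(plain), collapse = "\t")), con)
    write.table(plain, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(list(result_type = type, data = plain), path,
                         digits = NA, na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path)
    type <- sub("^# mutsteps_result: ", "", lines[1])
    cols <- strsplit(sub("^#", "", lines[2]), "\t", fixed = TRUE)[[1]]
    body <- lines[-(1:2)]
    if (!length(body)) {
      df <- as.data.frame(matrix(character(), ncol = length(cols),
                                 dimnames = list(NULL, cols)))
    } else {
      df <- read.delim(text = body, header = FALSE, col.names = cols,
                       sep = "\t", na.strings = "NA", quote = "")
    }
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    type <- payload$result_type
    df <- as.data.frame(payload$data)
  }
  if (!type %in% RESULT_TYPES) abort(paste0("unknown result type: ", type))
  restore_result_types(new_result_tbl(df, type))
}

# Doubles serialised at full precision so round trips are lossless.
fmt_full <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

# Column classes that read.delim cannot infer (e.g. all-NA numeric columns).
restore_result_types <- function(x) {
  num_cols <- c("ratio", "p_value", "q_value", "score", "pop_af")
  int_cols <- c("ns", "s", "driver_estimate", "set_size", "overlap",
                "rank", "n_mutations", "n_patients", "pos")
  for (col in intersect(num_cols, names(x))) x[[col]] <- as.numeric(x[[col]])
  for (col in intersect(int_cols, names(x))) x[[col]] <- as.integer(x[[col]])
  x
}
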