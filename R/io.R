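pileup_cols <- function() c("sample_id", "np", "ref", count_cols)

#' Read a pileup TSV
#'
#' Reads the package's pileup dialect: a header row with columns
#' `sample_id`, `np`, `ref`, then forward/reverse counts for each base
#' (`A_fwd`, `A_rev`, ..., `T_rev`), and optionally per-base mean quality
#' columns `q_A` .. `q_T` (0-40 scale). Positions are 1-based rCRS
#' coordinates. Malformed rows (positions out of range, negative counts)
#' and duplicated (sample, position) pairs are hard errors that name the
#' offending rows.
#'
#' @param path File path.
#' @return A pileup tibble.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  need <- pileup_cols()
  if (length(hdr) == 0 || !all(need %in% hdr)) {
    abort(sprintf("pileup header must contain: %s",
                  paste(need, collapse = ", ")))
  }
  x <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  x$np <- as.integer(x$np)
  bad <- which(is.na(x$np) | x$np < 1L | x$np > 16569L)
  if (length(bad)) {
    abort(sprintf("position out of range 1..16569 at data row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  cnt <- as.matrix(x[count_cols])
  bad <- which(rowSums(is.na(cnt) | cnt < 0) > 0)
  if (length(bad)) {
    abort(sprintf("negative or missing counts at data row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  dup <- duplicated(x[c("sample_id", "np")])
  if (any(dup)) {
    abort(sprintf("duplicated (sample_id, np) at data row(s): %s",
                  paste(head(which(dup), 5), collapse = ", ")))
  }
  as_tibble(x)
}

#' Write a pileup TSV
#' @param pileup Pileup tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  check_pileup(pileup)
  readr::write_tsv(pileup, path, progress = FALSE)
  invisible(path)
}

#' Read a sample manifest TSV
#'
#' Columns `sample_id`, `family_id`, `role` (mother/child), `tissue`
#' (buccal/blood); sample ids and (family, role, tissue) slots must be
#' unique.
#'
#' @param path File path.
#' @return A manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  m <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  check_manifest(m)
  as_tibble(m)
}

#' Write a sample manifest TSV
#' @param manifest Manifest tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  check_manifest(manifest)
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

pct2 <- function(x) ifelse(is.na(x), "ND", sprintf("%.2f", x))

#' Write a variant-call report TSV
#'
#' Human-readable report of reported calls in the vocabulary of published
#' heteroplasmy tables: major/minor allele, forward:reverse read support
#' and frequencies in percent to two decimals. Machine-precision values
#' stay in the [call_variants()] tibble.
#'
#' @param calls Output of [call_variants()].
#' @param path File path.
#' @param all Write every row rather than reported calls only.
#' @return `path`, invisibly.
#' @export
write_variant_report <- function(calls, path, all = FALSE) {
  x <- if (all) calls else dplyr::filter(calls, .data$reported)
  out <- tibble(
    sample_id = x$sample_id,
    np = x$np,
    major_allele = x$major_allele,
    major_freq_pct = pct2(100 * x$major_freq),
    minor_allele = x$minor_allele,
    minor_reads = sprintf("%d:%d", x$minor_fwd, x$minor_rev),
    minor_freq_pct = pct2(100 * x$minor_freq),
    total_coverage = x$total_coverage,
    status = x$status
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a classification report TSV
#'
#' One row per classified (family, position): label, carrier, the four slot
#' frequencies in percent ("ND" for non-detections), gene, region,
#' synonymous flag and primary-haplotype-change flag.
#'
#' @param sites Output of [classify_sites()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(sites, path) {
  out <- tibble(
    family_id = sites$family_id, np = sites$np, label = sites$label,
    carrier = ifelse(is.na(sites$carrier), "", sites$carrier),
    mother_buccal = pct2(sites$mother_buccal_freq),
    mother_blood = pct2(sites$mother_blood_freq),
    child_buccal = pct2(sites$child_buccal_freq),
    child_blood = pct2(sites$child_blood_freq),
    gene = sites$gene, region = sites$region_category,
    synonymous = dplyr::case_when(
      is.na(sites$synonymous) ~ "", sites$synonymous ~ "Y", TRUE ~ "N"),
    aa_change = ifelse(is.na(sites$aa_change), "", sites$aa_change),
    primary_haplotype_change = sites$primary_haplotype_change
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the cohort summary as JSON
#' @param summary Output of [cohort_summary()] (or any list).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export reported calls as VCF
#'
#' Convenience VCFv4.2 export of reported heteroplasmy calls (one record
#' per call; the variant allele fraction in INFO/AF, position coverage in
#' INFO/DP). The core interchange format of the package remains the pileup
#' TSV, which carries the full count vectors that a genotype-centric VCF
#' cannot.
#'
#' @param calls Output of [call_variants()]; needs the `ref` column.
#' @param path File path.
#' @param contig Contig name for the header/records. Default "chrM".
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, contig = "chrM") {
  x <- dplyr::filter(calls, .data$reported)
  if (!"ref" %in% names(x)) {
    x$ref <- substring(mt_genome(), x$np, x$np)
  }
  variant <- ifelse(x$minor_allele == x$ref, x$major_allele, x$minor_allele)
  af <- ifelse(x$minor_allele == x$ref, x$major_freq, x$minor_freq)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitohet",
    sprintf("##contig=<ID=%s,length=16569,assembly=NC_012920.1>", contig),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Variant allele fraction of total position coverage\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total position coverage\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample id\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.6g;DP=%d;SAMPLE=%s",
                 contig, x$np, x$ref, variant, af, x$total_coverage,
                 x$sample_id)
  readr::write_lines(c(hdr, rec), path)
  invisible(path)
}

#' Write / read a filter configuration as YAML
#'
#' A run's effective configuration is written next to its outputs so the
#' run can be reproduced exactly.
#'
#' @param config A [filter_config()].
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [filter_config()].
#' @export
write_filter_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_filter_config
#' @export
read_filter_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(filter_config, x)
}
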