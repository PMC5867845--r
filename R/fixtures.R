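#' Packaged transcription of the shared-heteroplasmy reference table
#'
#' Per-slot minor-variant frequencies (percent) for the 12 mother-child
#' pairs with shared heteroplasmy at 14 distinct positions, as published;
#' `minor_freq_pct` is `NA` where heteroplasmy was not detected. The
#' `major_allele` column records each sample's consensus allele (for sites
#' where the minor variant *is* the reference base, the consensus is the
#' SNP).
#'
#' @return A tibble, one row per (pair, np, sample).
#' @export
table1_shared <- function() {
  path <- system.file("extdata", "table1_shared_heteroplasmy.tsv",
                      package = "mitohet", mustWork = TRUE)
  readr::read_tsv(path, progress = FALSE, na = "NA",
                  col_types = readr::cols(
                    pair = "i", np = "i", ref = "c", major_allele = "c",
                    minor_allele = "c", sample_id = "c", role = "c",
                    tissue = "c", minor_freq_pct = "d"))
}

#' Packaged transcription of the differentiating-heteroplasmy reference table
#'
#' Full published read support for the 17 mother-child pairs with
#' differentiating heteroplasmy at 21 positions: major and minor allele
#' with forward/reverse read counts and frequencies for all four samples of
#' each pair (including the below-threshold metadata rows of the
#' non-carrier), plus the published gene annotation for carrier rows.
#'
#' @return A tibble, one row per (pair, np, sample).
#' @export
table2_differentiating <- function() {
  path <- system.file("extdata", "table2_differentiating_heteroplasmy.tsv",
                      package = "mitohet", mustWork = TRUE)
  readr::read_tsv(path, progress = FALSE, na = c("", "NA"),
                  col_types = readr::cols(
                    pair = "i", np = "i", ref = "c", sample_id = "c",
                    role = "c", tissue = "c", major_allele = "c",
                    major_fwd = "i", major_rev = "i", major_freq_pct = "d",
                    minor_allele = "c", minor_fwd = "i", minor_rev = "i",
                    minor_freq_pct = "d", gene = "c", synonymous = "c",
                    aa_change = "c"))
}

split_reads <- function(n) {
  fwd <- n %/% 2L
  cbind(fwd = fwd, rev = n - fwd)
}

#' Reconstruct cohort pileups from the packaged reference tables
#'
#' Renders the transcribed tables as a pileup + manifest pair for the full
#' 39-family cohort, suitable for [call_variants()] and [classify_sites()].
#'
#' * Rows of the differentiating table reconstruct read counts exactly as
#'   published (major and minor forward/reverse counts; the other two bases
#'   zero), so total coverage is the major+minor sum. Recomputed
#'   frequencies can differ from the published ones by a few hundredths of
#'   a percentage point because published denominators included unprinted
#'   third/fourth-allele reads.
#' * The shared table publishes frequencies only; its rows are synthesised
#'   at a fixed coverage of 10,000 (comfortably above the 2000-read
#'   reporting floor, consistent with the "typically greater than 10,000
#'   reads" coverage of those positions), where a two-decimal percentage is
#'   exactly representable: `minor reads = freq * 100`, split evenly across
#'   strands. Not-detected slots get zero minor reads.
#' * The 22 families appearing in either table are identified by their
#'   mother-blood sample id; the remaining families are emitted flat
#'   (reference allele only) at the same fixed coverage, as are all
#'   families at positions where they carry nothing.
#'
#' @param tables Which transcriptions to realise: `"both"` (default, the
#'   full cohort), `"table1"` or `"table2"`.
#' @param flat_coverage Coverage for synthesised and flat rows.
#' @param n_families Total cohort size (default 39).
#' @return A list `pileup`, `manifest`.
#' @export
fixture_pileups <- function(tables = c("both", "table1", "table2"),
                            flat_coverage = 10000L,
                            n_families = 39L) {
  tables <- match.arg(tables)
  t1 <- table1_shared()
  t2 <- table2_differentiating()
  validate_transcriptions(t1, t2)

  # family registry keyed by the mother-blood sample id
  reg1 <- t1 |> dplyr::distinct(.data$pair, .data$sample_id, .data$role,
                                .data$tissue)
  reg2 <- t2 |> dplyr::distinct(.data$pair, .data$sample_id, .data$role,
                                .data$tissue)
  fam_key <- function(reg) {
    reg |>
      dplyr::group_by(.data$pair) |>
      dplyr::mutate(family_id = .data$sample_id[.data$role == "mother" &
                                                  .data$tissue == "blood"]) |>
      dplyr::ungroup()
  }
  members <- dplyr::bind_rows(fam_key(reg1), fam_key(reg2)) |>
    dplyr::distinct(.data$family_id, .data$sample_id, .data$role,
                    .data$tissue)
  if (anyDuplicated(members[c("family_id", "role", "tissue")])) {
    abort("transcribed tables disagree on sample ids within a family")
  }

  n_flat <- n_families - dplyr::n_distinct(members$family_id)
  if (n_flat < 0) abort("`n_families` smaller than the number of transcribed families")
  flat_members <- tidyr::crossing(
    family_id = sprintf("SIM%02d", seq_len(n_flat) +
                          dplyr::n_distinct(members$family_id)),
    tibble(role = c("mother", "mother", "child", "child"),
           tissue = c("buccal", "blood", "buccal", "blood"))
  ) |>
    dplyr::mutate(sample_id = sprintf("%s-%s%s", .data$family_id,
                                      toupper(substr(.data$role, 1, 1)),
                                      c(buccal = "Bu", blood = "Bl")[.data$tissue]))
  manifest <- dplyr::bind_rows(members, flat_members) |>
    dplyr::select("sample_id", "family_id", "role", "tissue")

  use1 <- tables %in% c("both", "table1")
  use2 <- tables %in% c("both", "table2")
  nps <- sort(unique(c(if (use1) t1$np, if (use2) t2$np)))
  genome <- mt_genome()
  ref_at <- setNames(substring(genome, nps, nps), nps)

  # flat scaffold: every sample x position, all reads on the reference base
  scaffold <- tidyr::crossing(manifest["sample_id"], np = nps) |>
    dplyr::mutate(ref = unname(ref_at[as.character(.data$np)]))
  cnt0 <- matrix(0L, nrow(scaffold), 8,
                 dimnames = list(NULL, count_cols))
  fr <- split_reads(rep(as.integer(flat_coverage), nrow(scaffold)))
  for (b in bases4) {
    hit <- scaffold$ref == b
    cnt0[hit, paste0(b, "_fwd")] <- fr[hit, "fwd"]
    cnt0[hit, paste0(b, "_rev")] <- fr[hit, "rev"]
  }
  pile <- dplyr::bind_cols(scaffold, as_tibble(cnt0))

  overlay <- list()
  if (use1) {
    s1 <- t1 |> dplyr::mutate(
      minor_reads = ifelse(is.na(.data$minor_freq_pct), 0L,
                           as.integer(round(.data$minor_freq_pct / 100 *
                                              flat_coverage))),
      major_reads = as.integer(flat_coverage) - .data$minor_reads)
    overlay <- c(overlay, list(
      tibble(sample_id = s1$sample_id, np = s1$np,
             allele = s1$major_allele, reads = s1$major_reads),
      tibble(sample_id = s1$sample_id, np = s1$np,
             allele = s1$minor_allele, reads = s1$minor_reads)))
  }
  if (use2) {
    overlay <- c(overlay, list(
      tibble(sample_id = t2$sample_id, np = t2$np, allele = t2$major_allele,
             fwd = t2$major_fwd, rev = t2$major_rev),
      tibble(sample_id = t2$sample_id, np = t2$np, allele = t2$minor_allele,
             fwd = t2$minor_fwd, rev = t2$minor_rev)))
  }
  ov <- dplyr::bind_rows(overlay)
  if (nrow(ov)) {
    if (!"reads" %in% names(ov)) ov$reads <- NA_integer_
    if (!"fwd" %in% names(ov)) ov$fwd <- NA_integer_
    if (!"rev" %in% names(ov)) ov$rev <- NA_integer_
    miss <- is.na(ov$fwd)
    sp <- split_reads(ov$reads[miss])
    ov$fwd[miss] <- sp[, "fwd"]
    ov$rev[miss] <- sp[, "rev"]

    key_p <- paste(pile$sample_id, pile$np)
    # zero out overlaid (sample, np) cells, then add the table counts
    hit <- key_p %in% paste(ov$sample_id, ov$np)
    for (cl in count_cols) pile[[cl]][hit] <- 0L
    idx <- match(paste(ov$sample_id, ov$np), key_p)
    if (anyNA(idx)) abort("transcribed sample outside the manifest")
    for (b in bases4) {
      sel <- ov$allele == b
      fc <- paste0(b, "_fwd"); rc <- paste0(b, "_rev")
      pile[[fc]][idx[sel]] <- pile[[fc]][idx[sel]] + ov$fwd[sel]
      pile[[rc]][idx[sel]] <- pile[[rc]][idx[sel]] + ov$rev[sel]
    }
  }
  list(pileup = as_tibble(pile), manifest = manifest)
}

# light-weight integrity checks on the packaged transcriptions: row counts,
# printed reference bases against the packaged genome, frequency arithmetic
validate_transcriptions <- function(t1, t2) {
  genome <- mt_genome()
  ok1 <- substring(genome, t1$np, t1$np) == t1$ref
  ok2 <- substring(genome, t2$np, t2$np) == t2$ref
  if (!all(ok1) || !all(ok2)) {
    abort("packaged table transcription disagrees with the reference genome")
  }
  if (nrow(t1) != 56L || nrow(t2) != 84L) {
    abort("packaged table transcription has unexpected row count")
  }
  # published minor frequencies match the printed counts via the implied
  # total (major / major_freq), within print rounding
  tot_implied <- (t2$major_fwd + t2$major_rev) / (t2$major_freq_pct / 100)
  freq <- 100 * (t2$minor_fwd + t2$minor_rev) / tot_implied
  if (max(abs(freq - t2$minor_freq_pct)) > 0.05) {
    abort("packaged differentiating-table counts disagree with printed frequencies")
  }
  invisible(TRUE)
}
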