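#' Filter configuration for heteroplasmy calling
#'
#' Bundles the analytical-threshold / read-count / coverage / balance filter
#' stack applied to candidate minor variants. Defaults follow deep-coverage
#' practice for reporting mitochondrial point heteroplasmy at 2%: a variant
#' is examined once its fraction reaches the analytical threshold (1%), and
#' reported only if it is supported by at least `min_variant_reads` reads at
#' a position with at least `min_total_coverage` total reads, its
#' forward/reverse support is balanced within `max_balance_ratio`, and its
#' fraction reaches the reporting threshold (2%). The score-balance filter
#' (difference between mean quality of major- and minor-allele calls) only
#' applies when the pileup carries per-base quality columns.
#'
#' @param analytical_threshold Minimum minor-allele fraction at which a
#'   variant is considered at all. Default 0.01.
#' @param min_variant_reads Minimum number of reads supporting the minor
#'   allele. Default 40.
#' @param min_total_coverage Minimum total position coverage. Default 200.
#' @param max_balance_ratio Maximum allowed strand-balance ratio for the
#'   minor allele. Default 2.5.
#' @param balance_mode How the strand-balance ratio is computed.
#'   `"major_normalized"` (default) compares the minor allele's
#'   forward/reverse ratio against the major allele's, i.e. the odds ratio
#'   `max(a, b) / min(a, b)` with `a = minor_fwd * major_rev` and
#'   `b = minor_rev * major_fwd`: a minor variant is rejected only when its
#'   strand distribution is skewed *relative to the position's own*
#'   (amplicon positions are often legitimately strand-imbalanced as a
#'   whole). `"minor_only"` uses the raw
#'   `max(minor_fwd, minor_rev) / min(minor_fwd, minor_rev)`.
#' @param max_score_balance Maximum allowed absolute difference between the
#'   mean quality scores of major- and minor-allele calls (0-40 scale).
#'   Default 10; only applied when quality columns are present.
#' @param reporting_threshold Minimum minor-allele fraction for a call to be
#'   reported as heteroplasmy. Default 0.02.
#' @param excluded_positions Positions never called. Defaults to 310 (a
#'   C-stretch position whose apparent point heteroplasmy is confounded by
#'   length variation) and 3107 (the rCRS numbering placeholder).
#' @return A list with class `mitohet_filter_config`.
#' @export
filter_config <- function(analytical_threshold = 0.01,
                          min_variant_reads = 40L,
                          min_total_coverage = 200L,
                          max_balance_ratio = 2.5,
                          balance_mode = c("major_normalized", "minor_only"),
                          max_score_balance = 10,
                          reporting_threshold = 0.02,
                          excluded_positions = c(310L, 3107L)) {
  balance_mode <- match.arg(balance_mode)
  if (!(analytical_threshold > 0 &&
        analytical_threshold <= reporting_threshold &&
        reporting_threshold < 0.5)) {
    abort("need 0 < analytical_threshold <= reporting_threshold < 0.5")
  }
  if (min_variant_reads < 1L) abort("`min_variant_reads` must be >= 1")
  if (min_total_coverage < min_variant_reads) {
    abort("`min_total_coverage` must be >= `min_variant_reads`")
  }
  if (max_balance_ratio <= 0) abort("`max_balance_ratio` must be positive")
  structure(
    list(analytical_threshold = analytical_threshold,
         min_variant_reads = as.integer(min_variant_reads),
         min_total_coverage = as.integer(min_total_coverage),
         max_balance_ratio = max_balance_ratio,
         balance_mode = balance_mode,
         max_score_balance = max_score_balance,
         reporting_threshold = reporting_threshold,
         excluded_positions = as.integer(excluded_positions)),
    class = "mitohet_filter_config")
}

#' @export
print.mitohet_filter_config <- function(x, ...) {
  cat("<mitohet filter config>\n")
  cat(sprintf("  analytical threshold : %.3g\n", x$analytical_threshold))
  cat(sprintf("  reporting threshold  : %.3g\n", x$reporting_threshold))
  cat(sprintf("  min variant reads    : %d\n", x$min_variant_reads))
  cat(sprintf("  min total coverage   : %d\n", x$min_total_coverage))
  cat(sprintf("  max balance ratio    : %.3g (%s)\n", x$max_balance_ratio,
              x$balance_mode))
  cat(sprintf("  max score balance    : %.3g\n", x$max_score_balance))
  cat(sprintf("  excluded positions   : %s\n",
              paste(x$excluded_positions, collapse = ", ")))
  invisible(x)
}

bases4 <- c("A", "C", "G", "T")
count_cols <- as.vector(t(outer(bases4, c("fwd", "rev"), paste, sep = "_")))

check_pileup <- function(pileup) {
  need <- c("sample_id", "np", count_cols)
  miss <- setdiff(need, names(pileup))
  if (length(miss)) {
    abort(sprintf("pileup is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  cnt <- as.matrix(pileup[count_cols])
  if (anyNA(cnt) || any(cnt < 0)) abort("pileup counts must be non-negative")
  invisible(pileup)
}

#' Per-base allele fractions from a pileup
#'
#' Adds total coverage and per-base fractions to a pileup table. The
#' denominator is the total position coverage summed over all four bases and
#' both strands, so a minor-variant fraction is its share of *all* reads at
#' the position, not of the major+minor subset.
#'
#' @param pileup A pileup tibble (see [read_pileup()] for the dialect).
#' @return The input with `total_coverage` and `freq_A` .. `freq_T` columns
#'   appended; fractions are `NA` at zero-coverage rows.
#' @export
allele_frequencies <- function(pileup) {
  check_pileup(pileup)
  cnt <- vapply(bases4, function(b) {
    pileup[[paste0(b, "_fwd")]] + pileup[[paste0(b, "_rev")]]
  }, numeric(nrow(pileup)))
  cnt <- matrix(cnt, nrow = nrow(pileup),
                dimnames = list(NULL, bases4))
  tot <- rowSums(cnt)
  fr <- cnt / ifelse(tot > 0, tot, NA_real_)
  out <- pileup
  out$total_coverage <- as.integer(tot)
  for (b in bases4) out[[paste0("freq_", b)]] <- unname(fr[, b])
  out
}

#' Call heteroplasmic variants from per-position allele counts
#'
#' Determines the major (consensus) and minor allele at every pileup row and
#' pushes the minor allele through the filter cascade, in order: excluded
#' position, minimum total coverage, analytical threshold, minimum variant
#' reads, strand-balance ratio, score balance (only when quality columns
#' `q_A` .. `q_T` are present), and finally the reporting threshold. The
#' returned `status` records the outcome: `"reported"`, `"below_reporting"`,
#' `"insufficient_coverage"`, or `"failed_filter:<name>"` for the first
#' filter that rejected the call. Major-allele ties are broken
#' lexicographically (A < C < G < T) and announced with a message.
#'
#' @param pileup A pileup tibble.
#' @param config A [filter_config()].
#' @return A tibble with one row per pileup row: `sample_id`, `np`, `ref`
#'   (if present in the input), `total_coverage`, `major_allele`,
#'   `major_freq`, `minor_allele`, `minor_freq`, `minor_fwd`, `minor_rev`,
#'   `status`, and `reported` (logical convenience column). Frequencies are
#'   fractions, not percent.
#' @export
#' @examples
#' p <- tibble::tibble(sample_id = "s", np = 100L,
#'   A_fwd = 4900L, A_rev = 4900L, C_fwd = 100L, C_rev = 100L,
#'   G_fwd = 0L, G_rev = 0L, T_fwd = 0L, T_rev = 0L)
#' call_variants(p)
call_variants <- function(pileup, config = filter_config()) {
  check_pileup(pileup)
  n <- nrow(pileup)
  fwd <- as.matrix(pileup[paste0(bases4, "_fwd")])
  rev_ <- as.matrix(pileup[paste0(bases4, "_rev")])
  cnt <- fwd + rev_
  colnames(cnt) <- bases4
  tot <- rowSums(cnt)

  maj_i <- max.col(cnt, ties.method = "first")
  n_tied <- sum(cnt[cbind(seq_len(n), maj_i)] > 0 &
                  rowSums(cnt == cnt[cbind(seq_len(n), maj_i)]) > 1)
  if (n_tied > 0) {
    inform(sprintf(
      "major/minor allele tie at %d position(s); broken lexicographically (A < C < G < T)",
      n_tied))
  }
  cnt2 <- cnt
  cnt2[cbind(seq_len(n), maj_i)] <- -1L
  min_i <- max.col(cnt2, ties.method = "first")

  maj_cnt <- cnt[cbind(seq_len(n), maj_i)]
  min_cnt <- cnt[cbind(seq_len(n), min_i)]
  min_fwd <- fwd[cbind(seq_len(n), min_i)]
  min_rev <- rev_[cbind(seq_len(n), min_i)]
  maj_freq <- ifelse(tot > 0, maj_cnt / tot, NA_real_)
  min_freq <- ifelse(tot > 0, min_cnt / tot, NA_real_)

  maj_fwd <- fwd[cbind(seq_len(n), maj_i)]
  maj_rev <- rev_[cbind(seq_len(n), maj_i)]
  if (config$balance_mode == "major_normalized") {
    a <- as.numeric(min_fwd) * maj_rev
    b <- as.numeric(min_rev) * maj_fwd
  } else {
    a <- as.numeric(min_fwd)
    b <- as.numeric(min_rev)
  }
  balance <- ifelse(pmin(a, b) > 0, pmax(a, b) / pmin(a, b), Inf)

  has_q <- all(paste0("q_", bases4) %in% names(pileup))
  if (has_q) {
    qm <- as.matrix(pileup[paste0("q_", bases4)])
    score_diff <- abs(qm[cbind(seq_len(n), maj_i)] -
                        qm[cbind(seq_len(n), min_i)])
  } else {
    score_diff <- rep(0, n)
  }

  cfg <- config
  status <- dplyr::case_when(
    pileup$np %in% cfg$excluded_positions ~ "failed_filter:excluded",
    tot == 0 ~ "insufficient_coverage",
    tot < cfg$min_total_coverage ~ "failed_filter:min_total_coverage",
    min_freq < cfg$analytical_threshold ~ "failed_filter:analytical_threshold",
    min_cnt < cfg$min_variant_reads ~ "failed_filter:min_variant_reads",
    balance > cfg$max_balance_ratio ~ "failed_filter:balance_ratio",
    has_q & score_diff > cfg$max_score_balance ~ "failed_filter:score_balance",
    min_freq < cfg$reporting_threshold ~ "below_reporting",
    TRUE ~ "reported"
  )

  out <- tibble(
    sample_id = pileup$sample_id,
    np = as.integer(pileup$np),
    total_coverage = as.integer(tot),
    major_allele = ifelse(tot > 0, bases4[maj_i], NA_character_),
    major_freq = maj_freq,
    minor_allele = ifelse(tot > 0, bases4[min_i], NA_character_),
    minor_freq = min_freq,
    minor_fwd = as.integer(min_fwd),
    minor_rev = as.integer(min_rev),
    status = status,
    reported = status == "reported"
  )
  if ("ref" %in% names(pileup)) {
    out <- dplyr::mutate(out, ref = pileup$ref, .after = "np")
  }
  out
}

#' Per-position detection floor
#'
#' The effective minimum detectable minor-allele fraction at a position is
#' `max(analytical_threshold, min_variant_reads / total_coverage)`: below
#' that fraction a true variant cannot satisfy the read-count filter. A
#' position is adequate for reporting when the floor does not exceed the
#' reporting threshold, which at the defaults (40 reads, 2%) requires
#' coverage of at least 2000 reads.
#'
#' @inheritParams call_variants
#' @return A tibble `sample_id`, `np`, `total_coverage`, `floor`,
#'   `adequate_for_reporting`.
#' @export
detection_floor <- function(pileup, config = filter_config()) {
  check_pileup(pileup)
  cnt <- vapply(bases4, function(b) {
    pileup[[paste0(b, "_fwd")]] + pileup[[paste0(b, "_rev")]]
  }, numeric(nrow(pileup)))
  tot <- rowSums(matrix(cnt, nrow = nrow(pileup)))
  floor_ <- pmax(config$analytical_threshold,
                 ifelse(tot > 0, config$min_variant_reads / tot, Inf))
  tibble(sample_id = pileup$sample_id, np = as.integer(pileup$np),
         total_coverage = as.integer(tot), floor = floor_,
         adequate_for_reporting = floor_ <= config$reporting_threshold)
}
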