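#' Assumed substitution-error profile across a sample set
#'
#' Conservative per-position, per-nucleotide error estimate for deep
#' mitochondrial pileups: within each sample, every base call whose fraction
#' at a position is at or below 50% is assumed to be an error. For each
#' position and base, the rate is the sum of such calls across samples
#' divided by the summed coverage across samples, in percent; the average
#' rate per base pools numerator and denominator over all positions. Known
#' heteroplasmic variants are deliberately *not* excluded, so the estimate
#' is an upper bound (a true minor variant at fraction f <= 50% inflates the
#' rate at its position by f).
#'
#' Positions with zero coverage in a sample contribute nothing for that
#' sample; positions with zero coverage in every sample have undefined rates
#' and are flagged and excluded from averages.
#'
#' @param pileup Pileup tibble covering the samples and positions to
#'   profile.
#' @param reporting_threshold Fraction used to flag positions whose error
#'   rate rivals reported heteroplasmy (default 0.02). A message lists how
#'   many positions exceed it.
#' @return An object of class `mitohet_error_profile`: a list with
#'   `by_position` (tibble `np`, `coverage`, `rate_A` .. `rate_T`, percent),
#'   `average` (tibble `base`, `rate_pct`), `flagged` (positions whose rate
#'   exceeds the reporting threshold) and `zero_coverage` (positions with no
#'   reads anywhere).
#' @export
error_rates <- function(pileup, reporting_threshold = 0.02) {
  check_pileup(pileup)
  cnt <- vapply(bases4, function(b) {
    as.numeric(pileup[[paste0(b, "_fwd")]] + pileup[[paste0(b, "_rev")]])
  }, numeric(nrow(pileup)))
  cnt <- matrix(cnt, nrow = nrow(pileup), dimnames = list(NULL, bases4))
  tot <- rowSums(cnt)
  frac <- cnt / ifelse(tot > 0, tot, NA_real_)
  err <- cnt * (frac <= 0.5)      # the <= 50% rule, per sample per position
  err[tot == 0, ] <- 0

  np <- as.integer(pileup$np)
  cov_tab <- tapply(tot, np, sum)
  nps <- as.integer(names(cov_tab))
  cov_np <- as.numeric(cov_tab)
  err_np <- vapply(bases4, function(b) {
    as.vector(tapply(err[, b], np, sum))
  }, numeric(length(cov_np)))
  err_np <- matrix(err_np, ncol = 4, dimnames = list(NULL, bases4))
  zero <- cov_np == 0
  rates <- 100 * err_np / ifelse(cov_np > 0, cov_np, NA_real_)
  by_position <- tibble(
    np = nps, coverage = as.numeric(cov_np),
    rate_A = unname(rates[, "A"]), rate_C = unname(rates[, "C"]),
    rate_G = unname(rates[, "G"]), rate_T = unname(rates[, "T"])
  )

  average <- tibble(
    base = bases4,
    rate_pct = unname(100 * colSums(err_np[!zero, , drop = FALSE]) /
                        sum(cov_np[!zero]))
  )

  thr <- 100 * reporting_threshold
  flagged <- by_position |>
    tidyr::pivot_longer(dplyr::starts_with("rate_"),
                        names_to = "base", values_to = "rate_pct",
                        names_prefix = "rate_") |>
    dplyr::filter(!is.na(.data$rate_pct), .data$rate_pct > thr)
  if (nrow(flagged) > 0) {
    inform(sprintf(
      "%d position/base combination(s) have assumed error above the %.3g%% reporting threshold",
      nrow(flagged), thr))
  }
  if (any(zero)) {
    inform(sprintf("%d position(s) have zero coverage in every sample; rates undefined there",
                   sum(zero)))
  }
  structure(
    list(by_position = by_position, average = average, flagged = flagged,
         zero_coverage = nps[zero], reporting_threshold = reporting_threshold),
    class = "mitohet_error_profile")
}

#' @export
print.mitohet_error_profile <- function(x, ...) {
  cat("<mitohet error profile>\n")
  cat(sprintf("  positions profiled : %d\n", nrow(x$by_position)))
  for (i in seq_len(nrow(x$average))) {
    cat(sprintf("  average %s error   : %.4g%%\n",
                x$average$base[i], x$average$rate_pct[i]))
  }
  cat(sprintf("  positions above %.3g%% threshold: %d\n",
              100 * x$reporting_threshold, nrow(x$flagged)))
  invisible(x)
}

#' @export
tidy.mitohet_error_profile <- function(x, ...) {
  x$by_position |>
    tidyr::pivot_longer(dplyr::starts_with("rate_"),
                        names_to = "base", values_to = "rate_pct",
                        names_prefix = "rate_")
}

#' @export
glance.mitohet_error_profile <- function(x, ...) {
  out <- tidyr::pivot_wider(x$average, names_from = "base",
                            values_from = "rate_pct",
                            names_prefix = "rate_")
  out$n_positions <- nrow(x$by_position)
  out$n_flagged <- nrow(x$flagged)
  out
}

#' Error hotspots with sequence context
#'
#' Ranks positions by assumed error rate within each substituting base and
#' attaches the reference base, flanking sequence and motif flags. Rank
#' depth is configurable per base (deep mitochondrial error surveys use the
#' top 25 per base, extended for C to capture all rates above 2%).
#'
#' @param profile A `mitohet_error_profile`.
#' @param n_top Named integer vector: how many top rates to keep per base.
#' @return A tibble `base`, `rank`, `np`, `ref_base`, `rate_pct`,
#'   `adjacent_sequence`, `poly_a`, `poly_c`, `ggt`, with the motif-flag
#'   fractions of the kept sites in attribute `"motif_summary"`.
#' @export
error_hotspots <- function(profile,
                           n_top = c(A = 25L, C = 35L, G = 25L, T = 25L)) {
  stopifnot(inherits(profile, "mitohet_error_profile"))
  long <- tidy(profile) |> dplyr::filter(!is.na(.data$rate_pct))
  top <- long |>
    dplyr::group_by(.data$base) |>
    dplyr::arrange(dplyr::desc(.data$rate_pct), .data$np,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= n_top[dplyr::cur_group()$base]) |>
    dplyr::ungroup()
  genome <- mt_genome()
  ctx <- mt_adjacent_sequence(top$np)
  flags <- mt_motif_flags(ctx)
  out <- tibble(
    base = top$base, rank = top$rank, np = top$np,
    ref_base = substring(genome, top$np, top$np),
    rate_pct = top$rate_pct,
    adjacent_sequence = ctx,
    poly_a = flags$poly_a, poly_c = flags$poly_c, ggt = flags$ggt
  )
  attr(out, "motif_summary") <- tibble(
    n_sites = nrow(out),
    frac_poly_a = mean(out$poly_a),
    frac_poly_c = mean(out$poly_c),
    frac_ggt = mean(out$ggt)
  )
  out
}

#' Cohort depth-of-coverage assessment
#'
#' Summarises how much of the genome can be characterised at the reporting
#' threshold: the coverage floor is `min_variant_reads / reporting_threshold`
#' reads (2000 at the defaults), below which a minor variant at the
#' reporting threshold cannot satisfy the read-count filter.
#'
#' @param pileup Pileup tibble.
#' @param config A [filter_config()].
#' @return A list: `per_sample` (tibble `sample_id`,
#'   `n_positions_below_floor`, `mean_coverage`), `floor_coverage`,
#'   `fraction_adequate` (share of sample-position observations at or above
#'   the floor) and `mean_coverage`.
#' @export
coverage_assessment <- function(pileup, config = filter_config()) {
  check_pileup(pileup)
  fl <- detection_floor(pileup, config)
  floor_cov <- config$min_variant_reads / config$reporting_threshold
  per_sample <- fl |>
    dplyr::group_by(sample_id = .data$sample_id) |>
    dplyr::summarise(
      n_positions_below_floor = sum(.data$total_coverage < floor_cov),
      mean_coverage = mean(.data$total_coverage),
      .groups = "drop")
  list(per_sample = per_sample,
       floor_coverage = floor_cov,
       fraction_adequate = mean(fl$total_coverage >= floor_cov),
       mean_coverage = mean(fl$total_coverage))
}
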