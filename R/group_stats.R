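#' Minor-variant frequency sets per heteroplasmy class
#'
#' Assembles the per-observation frequency sets compared across the three
#' heteroplasmy classes. Sampling rules: every reported slot of a shared
#' site contributes one observation; a differentiating site contributes the
#' carrier's two tissue observations; a random site contributes its single
#' observation. Non-detections are excluded, not imputed as zero (only this
#' convention reproduces tabulated cohort means when some slots are below
#' detection).
#'
#' @param sites Output of [classify_sites()].
#' @return A long tibble `label`, `family_id`, `np`, `slot`, `freq_pct`.
#' @export
frequency_sets <- function(sites) {
  long <- sites |>
    dplyr::filter(.data$label %in% c("shared", "differentiating", "random")) |>
    tidyr::pivot_longer(
      cols = dplyr::ends_with("_freq"),
      names_to = "slot", values_to = "freq_pct",
      names_pattern = "(.*)_freq"
    ) |>
    dplyr::filter(!is.na(.data$freq_pct))
  keep <- long$label == "shared" |
    long$label == "random" |
    (long$label == "differentiating" &
       startsWith(long$slot, long$carrier))
  long[keep, c("label", "family_id", "np", "slot", "freq_pct")]
}

#' Welch two-sample comparison of heteroplasmy rates
#'
#' Unequal-variance two-sample t test (Welch-Satterthwaite degrees of
#' freedom, two-sided p) of minor-variant frequencies between two groups.
#'
#' @param x,y Numeric vectors of frequencies (percent), each of length >= 2.
#' @param labels Character pair naming the groups.
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`, `mean1`,
#'   `mean2`, `t_statistic`, `df`, `p_value`.
#' @export
#' @examples
#' welch_test(c(1, 2, 3), c(2, 3, 4, 5))
welch_test <- function(x, y, labels = c("x", "y")) {
  if (length(x) < 2 || length(y) < 2) {
    abort(sprintf("group '%s' has fewer than 2 observations",
                  labels[if (length(x) < 2) 1 else 2]))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(group1 = labels[1], group2 = labels[2],
         n1 = length(x), n2 = length(y),
         mean1 = mean(x), mean2 = mean(y),
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' All pairwise Welch comparisons between heteroplasmy classes
#'
#' @param freq_sets Output of [frequency_sets()].
#' @return A tibble with one row per comparable pair of classes; classes
#'   with fewer than two observations are skipped with a message.
#' @export
heteroplasmy_rate_tests <- function(freq_sets) {
  sets <- split(freq_sets$freq_pct, freq_sets$label)
  pairs <- utils::combn(c("shared", "differentiating", "random"), 2,
                        simplify = FALSE)
  out <- purrr::map(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    if (length(a) < 2 || length(b) < 2) {
      inform(sprintf("skipping %s vs %s: fewer than 2 observations",
                     p[1], p[2]))
      return(NULL)
    }
    welch_test(a, b, labels = p)
  })
  dplyr::bind_rows(out)
}

#' Band and fold-difference summary of differentiating sites
#'
#' Counts differentiating sites by 10% frequency band, tissue direction,
#' fold-difference band (<2x, 2-3x, >3x) and carrier.
#'
#' @param comparisons Output of [site_comparison()].
#' @return A one-row tibble of counts.
#' @export
band_summary <- function(comparisons) {
  fd <- comparisons$fold_difference
  tibble(
    n_sites = nrow(comparisons),
    both_lt10 = sum(comparisons$band == "both<10%"),
    both_gt10 = sum(comparisons$band == "both>10%"),
    mixed = sum(comparisons$band == "mixed"),
    buccal_higher = sum(comparisons$buccal_higher),
    fold_lt2 = sum(fd < 2, na.rm = TRUE),
    fold_2to3 = sum(fd >= 2 & fd <= 3, na.rm = TRUE),
    fold_gt3 = sum(fd > 3, na.rm = TRUE),
    carrier_mother = sum(comparisons$carrier == "mother"),
    carrier_child = sum(comparisons$carrier == "child")
  )
}
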