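#' Run the full heteroplasmy analysis
#'
#' Chains calling, quartet classification, tissue comparison, frequency-set
#' assembly, Welch comparisons and cohort tallies over a pileup + manifest
#' pair.
#'
#' @param pileup Pileup tibble (all samples, all positions of interest).
#' @param manifest Manifest tibble.
#' @param config A [filter_config()].
#' @return An object of class `mitohet_analysis`: a list with `calls`,
#'   `sites`, `comparisons`, `frequency_sets`, `rate_tests`, `bands`,
#'   `summary` and the `config` used.
#' @export
#' @examples
#' fx <- fixture_pileups()
#' res <- run_heteroplasmy_analysis(fx$pileup, fx$manifest)
#' res$summary$differentiating$n_pairs
run_heteroplasmy_analysis <- function(pileup, manifest,
                                      config = filter_config()) {
  calls <- call_variants(pileup, config)
  sites <- classify_sites(calls, manifest, config)
  comparisons <- site_comparison(sites)
  fsets <- frequency_sets(sites)
  tests <- if (nrow(fsets)) heteroplasmy_rate_tests(fsets) else tibble()
  bands <- band_summary(comparisons)
  summ <- cohort_summary(sites,
                         n_families = dplyr::n_distinct(manifest$family_id))
  structure(
    list(calls = calls, sites = sites, comparisons = comparisons,
         frequency_sets = fsets, rate_tests = tests, bands = bands,
         summary = summ, config = config),
    class = "mitohet_analysis")
}

#' @export
print.mitohet_analysis <- function(x, ...) {
  s <- x$summary
  cat("<mitohet analysis>\n")
  cat(sprintf("  families screened        : %d\n", s$n_families))
  cat(sprintf("  shared: %d pairs, %d distinct sites\n",
              s$shared$n_pairs, s$shared$n_distinct_np))
  cat(sprintf("  differentiating: %d pairs, %d sites (%d coding, %d CR)\n",
              s$differentiating$n_pairs, s$differentiating$n_sites,
              s$differentiating$n_coding, s$differentiating$n_control_region))
  cat(sprintf("  random: %d pairs, %d sites\n",
              s$random$n_pairs, s$random$n_sites))
  if (nrow(x$rate_tests)) {
    for (i in seq_len(nrow(x$rate_tests))) {
      r <- x$rate_tests[i, ]
      cat(sprintf("  %s (mean %.1f%%) vs %s (mean %.1f%%): p = %.2g\n",
                  r$group1, r$mean1, r$group2, r$mean2, r$p_value))
    }
  }
  invisible(x)
}

#' @export
tidy.mitohet_analysis <- function(x, ...) x$sites

#' @export
glance.mitohet_analysis <- function(x, ...) {
  s <- x$summary
  tibble(
    n_families = s$n_families,
    shared_pairs = s$shared$n_pairs,
    shared_sites = s$shared$n_distinct_np,
    differentiating_pairs = s$differentiating$n_pairs,
    differentiating_sites = s$differentiating$n_sites,
    random_pairs = s$random$n_pairs,
    random_sites = s$random$n_sites,
    unclassifiable = s$unclassifiable
  )
}

#' Buccal-versus-blood frequency plot for differentiating sites
#'
#' @param object A `mitohet_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mitohet_analysis <- function(object, ...) {
  cmp <- object$comparisons
  ggplot2::ggplot(cmp, ggplot2::aes(.data$blood_minor_freq,
                                    .data$buccal_minor_freq,
                                    colour = .data$carrier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "blood minor-variant frequency (%)",
                  y = "buccal minor-variant frequency (%)",
                  colour = "carrier",
                  title = "Differentiating heteroplasmy by tissue") +
    ggplot2::theme_minimal()
}

#' Per-position substitution-error plot
#'
#' One panel per substituting base, rate in percent against position, with
#' the average rate and the reporting threshold marked.
#'
#' @param object A `mitohet_error_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mitohet_error_profile <- function(object, ...) {
  long <- tidy(object)
  avg <- dplyr::rename(object$average, avg = "rate_pct")
  ggplot2::ggplot(long, ggplot2::aes(.data$np, .data$rate_pct)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(data = avg,
                        ggplot2::aes(yintercept = .data$avg),
                        colour = "red") +
    ggplot2::geom_hline(yintercept = 100 * object$reporting_threshold,
                        linetype = 2, colour = "blue") +
    ggplot2::facet_wrap(~base, ncol = 1) +
    ggplot2::labs(x = "nucleotide position",
                  y = "assumed substitution error (%)") +
    ggplot2::theme_minimal()
}
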