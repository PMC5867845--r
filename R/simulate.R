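#' Configuration for the germline-bottleneck cohort simulator
#'
#' The simulator emulates the statistical structure that deep-coverage
#' heteroplasmy studies of mother-child quartets assume: a founder (mother
#' germline) minor-variant frequency per seeded position; a single-generation
#' binomial germline bottleneck giving the child's germline frequency;
#' one further binomial segregation step per tissue (replicative
#' segregation); and deep multinomial read sampling with a uniform
#' substitution-noise floor. Empirical work places the human germline
#' bottleneck somewhere between a handful and a few tens of segregating
#' units; the default of 32 sits in the upper (~30-35) range, and is the
#' knob to turn for more or less inter-generation drift.
#'
#' @param n_families Number of mother-child quartets.
#' @param n_sites_per_family Seeded heteroplasmic positions per family.
#' @param bottleneck_size Effective mtDNA copy number of the germline
#'   bottleneck (binomial denominator). Default 32.
#' @param tissue_drift_size Named vector, effective segregation units per
#'   tissue. Buccal defaults to a smaller size than blood so buccal drifts
#'   harder, mirroring the higher heteroplasmy rates seen in buccal cells.
#' @param founder_freq_range Founder minor-variant frequency is drawn
#'   uniformly from this interval. Default `c(0.02, 0.5)`.
#' @param error_rate_per_base Mean substitution-noise fraction per read
#'   (split evenly across the three non-template bases). Default 5e-4, the
#'   order of magnitude of observed MiSeq substitution error.
#' @param coverage_median,coverage_sdlog Lognormal per-position coverage:
#'   median reads (default 24,000, deep-coverage scale) and log-sd.
#' @param genome_length Number of leading reference positions to simulate
#'   (full genome by default; smaller values give fast test cohorts).
#' @param strand_prob Probability a read is forward-strand. Default 0.5;
#'   move it to exercise the strand-balance filter.
#' @param hotspot_positions,hotspot_multiplier Optional positions whose
#'   noise rate is multiplied, to exercise error-hotspot detection.
#' @param seed Integer seed; identical configurations give identical
#'   cohorts.
#' @return A list with class `mitohet_sim_config`.
#' @export
sim_config <- function(n_families = 10L,
                       n_sites_per_family = 2L,
                       bottleneck_size = 32L,
                       tissue_drift_size = c(buccal = 200L, blood = 500L),
                       founder_freq_range = c(0.02, 0.5),
                       error_rate_per_base = 5e-4,
                       coverage_median = 24000,
                       coverage_sdlog = 0.5,
                       genome_length = 16569L,
                       strand_prob = 0.5,
                       hotspot_positions = integer(),
                       hotspot_multiplier = 1,
                       seed = 1L) {
  stopifnot(n_families >= 1, n_sites_per_family >= 0,
            bottleneck_size >= 1, all(tissue_drift_size >= 1),
            length(founder_freq_range) == 2,
            founder_freq_range[1] >= 0, founder_freq_range[2] <= 1,
            error_rate_per_base >= 0, error_rate_per_base <= 1,
            coverage_median > 0, genome_length >= 1,
            genome_length <= 16569, strand_prob > 0, strand_prob < 1)
  if (!all(c("buccal", "blood") %in% names(tissue_drift_size))) {
    abort("`tissue_drift_size` must be named with 'buccal' and 'blood'")
  }
  structure(
    list(n_families = as.integer(n_families),
         n_sites_per_family = as.integer(n_sites_per_family),
         bottleneck_size = as.integer(bottleneck_size),
         tissue_drift_size = tissue_drift_size,
         founder_freq_range = founder_freq_range,
         error_rate_per_base = error_rate_per_base,
         coverage_median = coverage_median,
         coverage_sdlog = coverage_sdlog,
         genome_length = as.integer(genome_length),
         strand_prob = strand_prob,
         hotspot_positions = as.integer(hotspot_positions),
         hotspot_multiplier = hotspot_multiplier,
         seed = as.integer(seed)),
    class = "mitohet_sim_config")
}

# binomial thinning: multinomial counts over the four bases, vectorized
# across positions
rmultinom4 <- function(cov, prob) {
  # prob: matrix n x 4, rows sum to 1
  n <- length(cov)
  out <- matrix(0L, n, 4, dimnames = list(NULL, bases4))
  rem <- cov
  prem <- rep(1, n)
  for (j in 1:3) {
    p <- ifelse(prem > 0, pmin(prob[, j] / prem, 1), 0)
    out[, j] <- rbinom(n, rem, p)
    rem <- rem - out[, j]
    prem <- prem - prob[, j]
  }
  out[, 4] <- rem
  out
}

#' Simulate a deep-coverage mother-child cohort
#'
#' Draws a cohort under [sim_config()] and renders it as a pileup in the
#' package's TSV dialect, together with the sample manifest and the ground
#' truth per seeded site (founder, post-bottleneck and per-tissue
#' frequencies, plus the label an ideal detector applying the reporting
#' threshold directly to the tissue frequencies would assign).
#'
#' Seeded positions are sampled away from the excluded positions (310,
#' 3107). Degenerate settings behave as expected: a bottleneck of 1 fixes or
#' loses every variant in the child, and very large drift sizes transmit
#' founder frequencies essentially unchanged.
#'
#' @param config A [sim_config()].
#' @param reporting_threshold Threshold used for the ground-truth expected
#'   label (default 0.02).
#' @return A list `pileup`, `manifest`, `truth` of tibbles.
#' @export
simulate_cohort <- function(config = sim_config(),
                            reporting_threshold = 0.02) {
  stopifnot(inherits(config, "mitohet_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config,
                                                     reporting_threshold))
}

simulate_cohort_impl <- function(cfg, reporting_threshold) {
  L <- cfg$genome_length
  genome <- substring(mt_genome(), 1L, L)
  ref <- strsplit(genome, "")[[1]]
  callable <- setdiff(which(ref != "N"), c(310L, 3107L))

  slots <- tibble(
    role = rep(c("mother", "mother", "child", "child"), 1),
    tissue = rep(c("buccal", "blood"), 2)
  )

  pileups <- list(); truths <- list(); manifests <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("FAM%03d", f)
    n_sites <- min(cfg$n_sites_per_family, length(callable))
    sites <- sort(sample(callable, n_sites))
    founder <- runif(n_sites, cfg$founder_freq_range[1],
                     cfg$founder_freq_range[2])
    child_germ <- rbinom(n_sites, cfg$bottleneck_size, founder) /
      cfg$bottleneck_size
    alt <- vapply(sites, function(p) {
      sample(setdiff(bases4, ref[p]), 1)
    }, character(1))

    tiss_freq <- list()
    for (i in seq_len(nrow(slots))) {
      role <- slots$role[i]; tissue <- slots$tissue[i]
      base_freq <- if (role == "mother") founder else child_germ
      m <- cfg$tissue_drift_size[[tissue]]
      tiss_freq[[paste(role, tissue, sep = "_")]] <-
        rbinom(n_sites, m, base_freq) / m
    }

    err <- rep(cfg$error_rate_per_base, L)
    if (length(cfg$hotspot_positions)) {
      hp <- intersect(cfg$hotspot_positions, seq_len(L))
      err[hp] <- pmin(err[hp] * cfg$hotspot_multiplier, 0.45)
    }

    for (i in seq_len(nrow(slots))) {
      role <- slots$role[i]; tissue <- slots$tissue[i]
      sid <- sprintf("%s-%s-%s", fam, substr(role, 1, 1), substr(tissue, 1, 2))
      cov <- as.integer(round(rlnorm(L, log(cfg$coverage_median),
                                     cfg$coverage_sdlog)))
      v <- numeric(L)
      v[sites] <- tiss_freq[[paste(role, tissue, sep = "_")]]
      altb <- rep(NA_character_, L)
      altb[sites] <- alt
      prob <- matrix(0, L, 4, dimnames = list(NULL, bases4))
      for (b in bases4) {
        is_ref <- ref == b
        is_alt <- !is.na(altb) & altb == b
        prob[, b] <- ifelse(is_ref, 1 - v - err,
                            ifelse(is_alt, v + err / 3, err / 3))
      }
      prob[ref == "N", ] <- 0.25  # placeholder position: uninformative reads
      prob <- pmax(prob, 0)       # a fixed variant (v = 1) zeroes the template
      prob <- prob / rowSums(prob)
      cnt <- rmultinom4(cov, prob)
      fwdm <- matrix(rbinom(4L * L, as.vector(cnt), cfg$strand_prob), L, 4)
      revm <- cnt - fwdm
      pl <- tibble(sample_id = sid, np = seq_len(L), ref = ref)
      for (j in 1:4) {
        pl[[paste0(bases4[j], "_fwd")]] <- as.integer(fwdm[, j])
        pl[[paste0(bases4[j], "_rev")]] <- as.integer(revm[, j])
      }
      pileups[[length(pileups) + 1L]] <- pl
      manifests[[length(manifests) + 1L]] <- tibble(
        sample_id = sid, family_id = fam, role = role, tissue = tissue)
    }

    # a site is "detected" in a slot when the minor fraction there reaches
    # the threshold; after fixation/loss the minor fraction is 0
    thr <- reporting_threshold
    minor_frac <- function(x) pmin(x, 1 - x)
    rep_mb <- minor_frac(tiss_freq$mother_buccal) >= thr
    rep_ml <- minor_frac(tiss_freq$mother_blood) >= thr
    rep_cb <- minor_frac(tiss_freq$child_buccal) >= thr
    rep_cl <- minor_frac(tiss_freq$child_blood) >= thr
    truths[[length(truths) + 1L]] <- tibble(
      family_id = fam, np = sites, ref = ref[sites], variant = alt,
      founder_freq = founder, child_germline_freq = child_germ,
      mother_buccal_freq = tiss_freq$mother_buccal,
      mother_blood_freq = tiss_freq$mother_blood,
      child_buccal_freq = tiss_freq$child_buccal,
      child_blood_freq = tiss_freq$child_blood,
      expected_label = label_from_pattern(rep_mb, rep_ml, rep_cb, rep_cl)
    )
  }
  list(pileup = dplyr::bind_rows(pileups),
       manifest = dplyr::bind_rows(manifests),
       truth = dplyr::bind_rows(truths))
}
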