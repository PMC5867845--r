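test_that("identical configurations give identical cohorts", {
  cfg <- sim_config(n_families = 2, genome_length = 300, seed = 99,
                    coverage_median = 2000)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_families = 2, genome_length = 300, seed = 100,
                     coverage_median = 2000)
  expect_false(identical(simulate_cohort(cfg2)$pileup, a$pileup))
})

test_that("a bottleneck of one fixes or loses every variant in the child", {
  cfg <- sim_config(n_families = 30, n_sites_per_family = 2,
                    bottleneck_size = 1, genome_length = 100,
                    coverage_median = 500, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$child_germline_freq %in% c(0, 1)))
})

test_that("bottleneck drift is unbiased with the binomial variance", {
  f <- 0.3; B <- 32L
  cfg <- sim_config(n_families = 3000, n_sites_per_family = 1,
                    bottleneck_size = B, genome_length = 4,
                    founder_freq_range = c(f, f),
                    coverage_median = 50, coverage_sdlog = 0.1, seed = 42)
  sim <- simulate_cohort(cfg)
  cg <- sim$truth$child_germline_freq
  expect_equal(length(cg), 3000L)
  expect_equal(mean(cg), f, tolerance = 0.01)
  v_expect <- f * (1 - f) / B
  expect_equal(var(cg), v_expect, tolerance = 0.08)
})

test_that("in the noise-free wide-drift limit every site is shared at ~founder", {
  cfg <- sim_config(n_families = 4, n_sites_per_family = 2,
                    bottleneck_size = 1e6L,
                    tissue_drift_size = c(buccal = 1e6L, blood = 1e6L),
                    founder_freq_range = c(0.1, 0.4),
                    error_rate_per_base = 0, genome_length = 500,
                    coverage_median = 20000, coverage_sdlog = 0.2, seed = 7)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$expected_label == "shared"))
  res <- run_heteroplasmy_analysis(sim$pileup, sim$manifest)
  got <- dplyr::inner_join(res$sites, sim$truth, by = c("family_id", "np"),
                           suffix = c("", ".true"))
  expect_equal(nrow(got), nrow(sim$truth))
  expect_true(all(got$label == "shared"))
  expect_equal(got$mother_buccal_freq / 100, got$founder_freq,
               tolerance = 0.05)
})

test_that("with no seeded heteroplasmy the pipeline stays silent", {
  for (err in c(5e-4, 2e-3)) {
    cfg <- sim_config(n_families = 2, n_sites_per_family = 0,
                      error_rate_per_base = err, genome_length = 2000,
                      coverage_median = 20000, seed = 11)
    sim <- simulate_cohort(cfg)
    calls <- call_variants(sim$pileup)
    expect_equal(sum(calls$reported), 0L)
  }
})

test_that("called frequencies track simulated tissue frequencies", {
  cfg <- sim_config(n_families = 25, n_sites_per_family = 4,
                    genome_length = 1000, coverage_median = 15000,
                    coverage_sdlog = 0.2, seed = 13)
  sim <- simulate_cohort(cfg)
  calls <- call_variants(sim$pileup) |>
    dplyr::inner_join(sim$manifest, by = "sample_id")
  truth_long <- sim$truth |>
    tidyr::pivot_longer(dplyr::ends_with("al_freq") | dplyr::ends_with("od_freq"),
                        names_to = "slot", values_to = "true_freq") |>
    dplyr::mutate(
      role = sub("_(buccal|blood)_freq$", "", slot),
      tissue = sub("^(mother|child)_", "", sub("_freq$", "", slot)))
  j <- dplyr::inner_join(calls, truth_long,
                         by = c("family_id", "np", "role", "tissue"))
  j <- dplyr::filter(j, true_freq >= 0.04, true_freq <= 0.5)
  expect_gt(nrow(j), 200)
  # expected called fraction: the true mix thinned by substitution noise,
  # plus the share of noise reads landing on the variant base
  e <- cfg$error_rate_per_base
  mu <- j$true_freq * (1 - e) + e / 3
  sd_bin <- sqrt(mu * (1 - mu) / j$total_coverage)
  within3 <- abs(j$minor_freq - mu) <= 3 * sd_bin + 1e-9
  expect_gte(mean(within3), 0.99)
})

test_that("expected labels are recovered away from the threshold boundary", {
  cfg <- sim_config(n_families = 30, n_sites_per_family = 2,
                    genome_length = 1500, coverage_median = 24000,
                    coverage_sdlog = 0.3, seed = 17)
  sim <- simulate_cohort(cfg)
  res <- suppressMessages(
    run_heteroplasmy_analysis(sim$pileup, sim$manifest))
  truth <- sim$truth |>
    dplyr::rowwise() |>
    dplyr::mutate(away = {
      m <- pmin(c(mother_buccal_freq, mother_blood_freq,
                  child_buccal_freq, child_blood_freq),
                1 - c(mother_buccal_freq, mother_blood_freq,
                      child_buccal_freq, child_blood_freq))
      all(m >= 0.04 | m <= 0.01)
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(away, !is.na(expected_label))
  got <- dplyr::left_join(truth, res$sites, by = c("family_id", "np"))
  expect_gt(nrow(got), 30)
  agree <- !is.na(got$label) & got$label == got$expected_label
  expect_gte(mean(agree), 0.95)
})

test_that("published read counts survive the fixture round trip exactly", {
  fx <- fixture_pileups("both")
  t2 <- table2_differentiating()
  key <- paste(fx$pileup$sample_id, fx$pileup$np)
  idx <- match(paste(t2$sample_id, t2$np), key)
  expect_false(anyNA(idx))
  for (i in seq_len(nrow(t2))) {
    row <- fx$pileup[idx[i], ]
    expect_equal(row[[paste0(t2$major_allele[i], "_fwd")]], t2$major_fwd[i])
    expect_equal(row[[paste0(t2$major_allele[i], "_rev")]], t2$major_rev[i])
    expect_equal(row[[paste0(t2$minor_allele[i], "_fwd")]], t2$minor_fwd[i])
    expect_equal(row[[paste0(t2$minor_allele[i], "_rev")]], t2$minor_rev[i])
  }
})

test_that("fixture frequencies reproduce the published values", {
  fx <- fixture_pileups("both")
  calls <- call_variants(fx$pileup)
  # shared-table slots synthesised at coverage 10,000 are exact
  t1 <- table1_shared() |> dplyr::filter(!is.na(minor_freq_pct))
  j1 <- dplyr::inner_join(calls, t1, by = c("sample_id", "np"))
  expect_equal(nrow(j1), nrow(t1))
  expect_equal(100 * j1$minor_freq, j1$minor_freq_pct, tolerance = 1e-8)
  # differentiating-table carrier slots: printed denominators carried a few
  # unprinted third-allele reads, so agreement is to ~0.1 percentage points
  t2 <- table2_differentiating() |> dplyr::filter(!is.na(gene))
  j2 <- dplyr::inner_join(calls, t2, by = c("sample_id", "np"))
  expect_equal(nrow(j2), nrow(t2))
  expect_lt(max(abs(100 * j2$minor_freq - j2$minor_freq_pct)), 0.1)
})

test_that("table transcriptions pass their integrity checks", {
  expect_equal(nrow(table1_shared()), 56L)
  expect_equal(nrow(table2_differentiating()), 84L)
  expect_silent(fx <- fixture_pileups("table1"))
  expect_equal(dplyr::n_distinct(fx$manifest$family_id), 39L)
  expect_equal(nrow(fx$manifest), 156L)
})
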