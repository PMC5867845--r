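test_that("allele fractions equal a brute-force recount on random pileups", {
  withr::local_seed(42)
  n <- 1000
  cnt <- matrix(rpois(8 * n, lambda = 50), n, 8)
  pl <- tibble::as_tibble(as.data.frame(cnt)) |>
    rlang::set_names(c("A_fwd", "A_rev", "C_fwd", "C_rev",
                       "G_fwd", "G_rev", "T_fwd", "T_rev")) |>
    dplyr::mutate(sample_id = "s", np = dplyr::row_number(), .before = 1)
  fr <- allele_frequencies(pl)
  for (i in sample(n, 50)) {
    tot <- sum(cnt[i, ])
    expect_equal(fr$total_coverage[i], tot)
    expect_equal(fr$freq_C[i], (cnt[i, 3] + cnt[i, 4]) / tot)
  }
  expect_equal(fr$freq_A + fr$freq_C + fr$freq_G + fr$freq_T,
               rep(1, n))
})

test_that("a single-allele pileup is monomorphic at fraction 1", {
  fr <- allele_frequencies(pileup_row(T = 100))
  expect_equal(fr$freq_T, 1)
  expect_equal(fr$freq_A, 0)
})

test_that("published frequency convention: minor over total position coverage", {
  t2 <- table2_differentiating()
  # printed major counts and major percentage imply the full denominator
  # (which included third/fourth-allele reads); the printed minor
  # percentage is then minor reads over that same total
  tot_implied <- (t2$major_fwd + t2$major_rev) / (t2$major_freq_pct / 100)
  recomputed <- 100 * (t2$minor_fwd + t2$minor_rev) / tot_implied
  expect_lt(max(abs(recomputed - t2$minor_freq_pct)), 0.05)
  # the flagship worked example: 20.11% minor C at np 2746
  row1 <- t2[t2$np == 2746 & t2$tissue == "buccal" & t2$role == "mother", ]
  expect_equal(round(100 * (row1$minor_fwd + row1$minor_rev) /
                       ((row1$major_fwd + row1$major_rev) /
                          (row1$major_freq_pct / 100)), 2), 20.11)
})

# independent sequential re-statement of the filter cascade
oracle_status <- function(np, counts, fwd, rev, cfg) {
  tot <- sum(counts)
  if (np %in% cfg$excluded_positions) return("failed_filter:excluded")
  if (tot == 0) return("insufficient_coverage")
  ord <- order(counts, decreasing = TRUE)  # stable: ties fall lexicographic
  maj <- ord[1]; min_ <- ord[2]
  f <- counts[min_] / tot
  if (tot < cfg$min_total_coverage) return("failed_filter:min_total_coverage")
  if (f < cfg$analytical_threshold) return("failed_filter:analytical_threshold")
  if (counts[min_] < cfg$min_variant_reads) return("failed_filter:min_variant_reads")
  a <- fwd[min_] * rev[maj]; b <- rev[min_] * fwd[maj]
  if (min(a, b) == 0 || max(a, b) / min(a, b) > cfg$max_balance_ratio) {
    return("failed_filter:balance_ratio")
  }
  if (f < cfg$reporting_threshold) return("below_reporting")
  "reported"
}

test_that("filter cascade agrees with a brute-force oracle over a grid", {
  cfg <- filter_config()
  grid <- expand.grid(
    coverage = c(150, 200, 1000, 1999, 2000, 4000),
    minor = c(0, 10, 39, 40, 80, 200),
    split = c(0, 0.2, 0.5)  # minor forward-strand share
  )
  grid <- grid[grid$minor < grid$coverage, ]
  rows <- list(); expected <- character(0)
  for (i in seq_len(nrow(grid))) {
    cov <- grid$coverage[i]; m <- grid$minor[i]; s <- grid$split[i]
    mf <- round(m * s); mr <- m - mf
    Mf <- floor((cov - m) / 2); Mr <- cov - m - Mf
    rows[[i]] <- pileup_row(np = 5000L, A = c(Mf, Mr), G = c(mf, mr))
    counts <- c(A = Mf + Mr, C = 0, G = mf + mr, T = 0)
    expected[i] <- oracle_status(5000L, counts,
                                 c(Mf, 0, mf, 0), c(Mr, 0, mr, 0), cfg)
  }
  calls <- call_variants(dplyr::bind_rows(rows), cfg)
  expect_equal(calls$status, expected)
})

test_that("boundary cases of the cascade behave as specified", {
  cfg <- filter_config()
  # 39 minor reads of 2000: above the analytical threshold but one read
  # short of the count filter
  c1 <- call_variants(pileup_row(np = 5000, A = 1961, G = 39), cfg)
  expect_equal(c1$status, "failed_filter:min_variant_reads")
  # 40 of 2000 balanced: exactly the 2% reporting threshold
  c2 <- call_variants(pileup_row(np = 5000, A = 1960, G = 40), cfg)
  expect_equal(c2$status, "reported")
  # excluded positions are never called
  c3 <- call_variants(pileup_row(np = 310, A = 5000, G = 5000), cfg)
  expect_equal(c3$status, "failed_filter:excluded")
  # zero coverage
  c4 <- call_variants(pileup_row(np = 5000), cfg)
  expect_equal(c4$status, "insufficient_coverage")
  # one-direction minor fails strand balance even against a balanced major
  c5 <- call_variants(pileup_row(np = 5000, A = c(4000, 4000), G = c(120, 0)),
                      cfg)
  expect_equal(c5$status, "failed_filter:balance_ratio")
})

test_that("balance ratio is assessed relative to the major allele's strands", {
  cfg <- filter_config()
  # a position that is strand-skewed as a whole: minor 31:139 mirrors major
  # 1350:3677, so the minor variant is genuine
  c1 <- call_variants(pileup_row(np = 200 + 1, A = c(31, 139),
                                 G = c(1350, 3677)), cfg)
  expect_equal(c1$status, "reported")
  # under the raw minor-only reading the same pileup is rejected
  cfg2 <- filter_config(balance_mode = "minor_only")
  c2 <- call_variants(pileup_row(np = 200 + 1, A = c(31, 139),
                                 G = c(1350, 3677)), cfg2)
  expect_equal(c2$status, "failed_filter:balance_ratio")
})

test_that("quality score balance is applied only when quality data exist", {
  cfg <- filter_config()
  pl <- pileup_row(np = 5000, A = 9000, G = 1000)
  pl$q_A <- 38; pl$q_C <- 0; pl$q_G <- 20; pl$q_T <- 0
  expect_equal(call_variants(pl, cfg)$status, "failed_filter:score_balance")
  pl$q_G <- 30
  expect_equal(call_variants(pl, cfg)$status, "reported")
  expect_equal(call_variants(dplyr::select(pl, -dplyr::starts_with("q_")),
                             cfg)$status, "reported")
})

test_that("major-allele ties break lexicographically with a message", {
  pl <- pileup_row(np = 5000, C = 5000, G = 5000)
  expect_message(calls <- call_variants(pl), "tie")
  expect_equal(calls$major_allele, "C")
  expect_equal(calls$minor_allele, "G")
})

test_that("the cascade is monotone in minor reads at fixed coverage", {
  cfg <- filter_config()
  cov <- 4000L
  statuses <- vapply(seq(0, 400, by = 8), function(m) {
    call_variants(pileup_row(np = 5000, A = cov - m, G = m), cfg)$status
  }, character(1))
  reported <- statuses == "reported"
  # once reported, stays reported as minor support grows
  expect_true(all(diff(reported) >= 0))
})

test_that("every reported call satisfies all thresholds simultaneously", {
  withr::local_seed(7)
  n <- 400
  pl <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    cov <- sample(100:5000, 1)
    m <- rbinom(1, cov, runif(1, 0, 0.06))
    pileup_row(np = sample(c(1:309, 311:3106), 1),
               A = c(floor((cov - m) / 2), ceiling((cov - m) / 2)),
               T = c(rbinom(1, m, 0.5), 0) + c(0, 0)) |>
      dplyr::mutate(T_rev = m - T_fwd)
  }))
  cfg <- filter_config()
  calls <- call_variants(pl, cfg)
  rep_ <- dplyr::filter(calls, reported)
  if (nrow(rep_)) {
    expect_true(all(rep_$minor_freq >= cfg$reporting_threshold))
    expect_true(all(rep_$minor_fwd + rep_$minor_rev >= cfg$min_variant_reads))
    expect_true(all(rep_$total_coverage >= cfg$min_total_coverage))
  }
})

test_that("detection floor switches arms at the documented coverage", {
  cfg <- filter_config()
  fl <- detection_floor(dplyr::bind_rows(
    pileup_row(np = 1, A = 2000),
    pileup_row(np = 2, A = 1999),
    pileup_row(np = 3, A = 4000),
    pileup_row(np = 4, A = 8000)), cfg)
  expect_equal(fl$floor, c(0.02, 40 / 1999, 0.01, 0.01))
  expect_equal(fl$adequate_for_reporting, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("filter configuration validates its invariants", {
  expect_error(filter_config(analytical_threshold = 0.05,
                             reporting_threshold = 0.02), "threshold")
  expect_error(filter_config(min_total_coverage = 10,
                             min_variant_reads = 40), "min_total_coverage")
  expect_error(filter_config(reporting_threshold = 0.6), "threshold")
})
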