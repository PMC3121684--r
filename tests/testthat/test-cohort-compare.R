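test_that("lifetime groups split at PSI 2 and 5 with inclusive boundaries", {
  expect_equal(as.character(assign_lifetime_group(c(1.4, 2.0, 5.0, 3.7, 7))),
               c("short", "short", "long", "intermediate", "long"))
  expect_true(is.na(assign_lifetime_group(NA_real_)))
  expect_error(assign_lifetime_group(0.5), "PSI")
})

test_that("mann_whitney matches the textbook cases", {
  a <- c(2.2, 3.1, 4.0, 5.3)
  mw <- mann_whitney(a, a)
  expect_equal(mw$statistic, length(a)^2 / 2)
  expect_gt(mw$p.value, 0.95)
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p.value, 0.1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("mann_whitney agrees with the enumeration oracle on small samples", {
  set.seed(29)
  for (i in 1:25) {
    a <- runif(sample(2:9, 1))
    b <- runif(sample(2:9, 1))
    mw <- mann_whitney(a, b)
    or <- exact_mw(a, b)
    expect_equal(mw$statistic, or$statistic)
    expect_lt(abs(mw$p.value - or$p.value), 1e-3)
  }
})

test_that("normal approximation tracks the exact p at n = 8 per group", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(approx_p - exact_mw(a, b)$p.value), 2e-2)
  }
})

test_that("kolmogorov_smirnov D matches direct ECDF evaluation", {
  x <- c(2.2, 3.1, 4.0)
  expect_equal(kolmogorov_smirnov(x, x)$statistic, 0)
  expect_equal(kolmogorov_smirnov(c(1, 2, 3), c(10, 11, 12))$statistic, 1)
  expect_equal(kolmogorov_smirnov(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
})

test_that("compare_metric uses the right unit of observation", {
  set.seed(41)
  cfg <- synthetic_config(n_short = 60, n_long = 60)
  p <- generate_proteome(cfg, 17)
  scan <- summarize_proteome(p$records, p$profiles)
  psi <- setNames(p$records$psi, p$records$protein_id)
  per_prot <- compare_metric(scan, psi, "normalized_score")
  expect_equal(per_prot$n_short + per_prot$n_long, nrow(scan$summary))
  per_seg <- compare_metric(scan, psi, "segment_length")
  expect_equal(per_seg$n_short + per_seg$n_long, nrow(scan$segments))
  # planted effect: short group shifted to higher aggregation
  expect_lt(per_prot$mw_p, 0.001)
  expect_equal(per_prot$direction, 1)
})

test_that("constant metric in both groups gives D = 0 and p near 1", {
  scan <- fake_scan(sprintf("P%02d", 1:20), length = rep(100, 20),
                    normalized_score = rep(2.5, 20))
  psi <- setNames(c(rep(1.5, 10), rep(6, 10)), scan$summary$protein_id)
  res <- compare_metric(scan, psi, "normalized_score")
  expect_equal(res$ks_statistic, 0)
  expect_gt(res$ks_p, 0.99)
  expect_equal(res$direction, 0)
})

test_that("comparison errors name a group with too few observations", {
  scan <- fake_scan(c("P1", "P2", "P3"), length = rep(100, 3),
                    normalized_score = c(1, 2, 3))
  psi <- setNames(c(1.5, 6, 6), scan$summary$protein_id)
  expect_error(compare_metric(scan, psi, "normalized_score"), "'short'")
})

test_that("length restriction is a no-op when all proteins are short enough", {
  set.seed(43)
  scan <- fake_scan(sprintf("P%02d", 1:40),
                    length = sample(80:250, 40, replace = TRUE),
                    normalized_score = runif(40, 0, 6))
  psi <- setNames(c(rep(1.5, 20), rep(6, 20)), scan$summary$protein_id)
  expect_equal(length_restricted_compare(scan, psi, "normalized_score", 300),
               compare_metric(scan, psi, "normalized_score"))
  expect_error(length_restricted_compare(scan, psi, "normalized_score", 0))
})

test_that("length restriction weakens an effect carried by long proteins", {
  set.seed(47)
  n <- 120
  len <- c(sample(100:290, n / 2, replace = TRUE),
           sample(310:600, n / 2, replace = TRUE))
  psi <- rep(c(1.5, 6), n / 2)
  # only proteins longer than 300 carry the group difference
  score <- runif(n, 1, 2) + ifelse(len > 300 & psi <= 2, 2, 0)
  scan <- fake_scan(sprintf("P%03d", 1:n), len, score)
  names(psi) <- scan$summary$protein_id
  full <- compare_metric(scan, psi, "normalized_score")
  restr <- length_restricted_compare(scan, psi, "normalized_score", 300)
  expect_gt(restr$mw_p, full$mw_p)
})

test_that("length-binned profile conserves counts and shows a planted gap", {
  set.seed(53)
  n <- 200
  len <- sample(50:550, n, replace = TRUE)
  psi <- rep(c(1.5, 6), n / 2)
  score <- rnorm(n, ifelse(psi <= 2, 4, 2), 0.3)  # length-independent gap
  scan <- fake_scan(sprintf("P%03d", 1:n), len, score)
  names(psi) <- scan$summary$protein_id
  prof <- length_binned_profile(scan, psi, bin_width = 100, min_n = 5)
  expect_equal(sum(prof$n), n)
  wide <- merge(prof[prof$group == "short", c("bin_start", "mean_normalized_score", "n")],
                prof[prof$group == "long", c("bin_start", "mean_normalized_score", "n")],
                by = "bin_start", suffixes = c("_s", "_l"))
  pop <- wide[wide$n_s >= 5 & wide$n_l >= 5, ]
  expect_gt(nrow(pop), 2)
  expect_true(all(pop$mean_normalized_score_s > pop$mean_normalized_score_l))
  one <- length_binned_profile(fake_scan("P1", 120, 3.3),
                               c(P1 = 1.5), bin_width = 100)
  expect_equal(one$n, 1L)
  expect_equal(one$mean_normalized_score, 3.3)
})

test_that("expression stratification separates confound from genuine effect", {
  set.seed(59)
  n <- 400
  psi <- rep(c(1.5, 6), n / 2)
  ids <- sprintf("P%03d", 1:n)
  # scenario A: expression shifted between groups, no aggregation effect
  expr_a <- rnorm(n, ifelse(psi <= 2, 5, 7), 1)
  score_a <- rnorm(n, 3, 0.5)
  scan_a <- fake_scan(ids, rep(200, n), score_a)
  strat_a <- expression_stratified_compare(scan_a, setNames(psi, ids),
                                           setNames(expr_a, ids))
  expect_equal(sum(strat_a$bins$n), n)
  wide_a <- merge(strat_a$bins[strat_a$bins$group == "short", ],
                  strat_a$bins[strat_a$bins$group == "long", ],
                  by = "bin", suffixes = c("_s", "_l"))
  pop_a <- wide_a[wide_a$n_s >= 20 & wide_a$n_l >= 20, ]
  expect_gt(nrow(pop_a), 0)
  expect_true(all(abs(pop_a$mean_normalized_score_s -
                        pop_a$mean_normalized_score_l) < 0.5))
  # the marginal densities do differ
  es <- strat_a$expression_summary
  expect_gt(abs(es$mean_expression[es$group == "short"] -
                  es$mean_expression[es$group == "long"]), 1)
  # scenario B: aggregation gap independent of expression
  score_b <- rnorm(n, ifelse(psi <= 2, 4, 2), 0.3)
  strat_b <- expression_stratified_compare(fake_scan(ids, rep(200, n), score_b),
                                           setNames(psi, ids),
                                           setNames(rnorm(n, 6, 1), ids))
  wide_b <- merge(strat_b$bins[strat_b$bins$group == "short", ],
                  strat_b$bins[strat_b$bins$group == "long", ],
                  by = "bin", suffixes = c("_s", "_l"))
  pop_b <- wide_b[wide_b$n_s >= 10 & wide_b$n_l >= 10, ]
  expect_gt(nrow(pop_b), 1)
  expect_true(all(pop_b$mean_normalized_score_s >
                    pop_b$mean_normalized_score_l))
})
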