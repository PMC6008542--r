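test_that("KS check flags non-gaussian samples and passes gaussian ones", {
  set.seed(21)
  pass <- sum(vapply(1:20, function(i) ks_nongaussianity(rnorm(1000)) > 0.05,
                     TRUE))
  expect_gte(pass, 18)
  expect_lt(ks_nongaussianity(rexp(1000)), 0.01)
  expect_error(ks_nongaussianity(c(1, 2, 3)),
               class = "scclfp_insufficient_data_error")
  expect_true(is.na(ks_nongaussianity(rep(2, 10))))
})

test_that("signed-rank test reproduces hand-enumerated cases", {
  r <- signed_rank_exact(1:6)
  expect_equal(r$statistic_W, 21)
  expect_equal(r$p_two_sided, 2 / 64)
  expect_equal(r$n, 6)

  # zeros are dropped before ranking
  r2 <- signed_rank_exact(c(0, 0, 5))
  expect_equal(r2$n, 1)
  expect_equal(r2$statistic_W, 1)
  expect_equal(r2$p_two_sided, 1)

  # perfectly symmetric pairs carry no evidence
  expect_equal(signed_rank_exact(c(-3, 3))$p_two_sided, 1)
  expect_equal(signed_rank_exact(c(-1, 1, -2, 2))$p_two_sided, 1)

  expect_error(signed_rank_exact(c(0, 0)), class = "scclfp_all_zero_error")
})

test_that("signed-rank p equals brute-force enumeration over sign patterns", {
  set.seed(22)
  pool <- c(-3, -2, -1, -0.5, 0.5, 1, 1, 2, 2.5, 3, 4)
  for (i in 1:30) {
    n <- sample(3:10, 1)
    x <- sample(pool, n, replace = TRUE)
    expect_equal(signed_rank_exact(x)$p_two_sided, oracle_signed_rank_p(x),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank p is invariant under order-preserving magnitude growth", {
  set.seed(23)
  for (i in 1:20) {
    x <- round(rnorm(sample(4:9, 1)), 2)
    x <- x[x != 0]
    d <- runif(1, 0.1, 3)
    shifted <- x + sign(x) * d # signs and magnitude order both preserved
    expect_equal(signed_rank_exact(shifted)$p_two_sided,
                 signed_rank_exact(x)$p_two_sided)
  }
})

test_that("signed-rank p-values are valid under the null", {
  set.seed(24)
  p <- vapply(1:400, function(i) signed_rank_exact(rnorm(10))$p_two_sided, 0)
  for (t in c(0.02, 0.05, 0.1, 0.2, 0.5))
    expect_lte(mean(p <= t), t + 2 / 1024 + 0.045)
})

test_that("rank-sum-vs-zero reproduces hand-enumerated cases", {
  r <- rank_sum_vs_zero_exact(c(1, 2, 3))
  expect_equal(r$statistic_W, 15)
  expect_equal(r$p_two_sided, 0.1)
  expect_equal(rank_sum_vs_zero_exact(rep(0, 4))$p_two_sided, 1)
})

test_that("rank-sum p equals brute-force enumeration over group assignments", {
  set.seed(25)
  pool <- c(-2, -1, 0, 0.5, 1, 1, 2, 3)
  for (i in 1:30) {
    n <- sample(2:7, 1)
    x <- sample(pool, n, replace = TRUE)
    expect_equal(rank_sum_vs_zero_exact(x)$p_two_sided, oracle_rank_sum_p(x))
  }
})

test_that("Hedges' g applies the small-sample correction", {
  expect_equal(hedges_g(c(2, 4, 6)), (4 / 2) * (1 - 3 / 7))
  x <- rnorm(20)
  expect_equal(hedges_g(x - mean(x)), 0)
  expect_equal(hedges_g(-x), -hedges_g(x))
  expect_equal(hedges_g_paired(c(3, 5, 7), c(1, 1, 1)), hedges_g(c(2, 4, 6)))
  expect_error(hedges_g(c(2, 2, 2)), class = "scclfp_degenerate_sample_error")
  expect_error(hedges_g(3), class = "scclfp_insufficient_data_error")
})

test_that("Bonferroni threshold is alpha over the family size", {
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_equal(bonferroni_threshold(0.07, 1), 0.07)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
})

test_that("outcome correlation reports both Pearson and Spearman", {
  lin <- correlate_with_outcome(1:8, 3 + 2 * (1:8))
  expect_equal(lin$pearson$r, 1)
  expect_equal(lin$spearman$rho, 1)
  anti <- correlate_with_outcome(1:8, exp(-(1:8)))
  expect_equal(anti$spearman$rho, -1)
  # NA times excluded pairwise
  mixed <- correlate_with_outcome(1:6, c(2, 4, NA, 8, 10, 12))
  expect_equal(mixed$n, 5)
  expect_error(correlate_with_outcome(1:3, 1:3),
               class = "scclfp_insufficient_data_error")
})

test_that("correlation recovers a generated association at n = 11", {
  set.seed(26)
  rs <- replicate(500, {
    z <- rnorm(11)
    x <- z + rnorm(11, sd = sqrt(1 / 0.36 - 1))
    correlate_with_outcome(x, z)$pearson$r
  })
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("group table flags the designed cells and pairs patients correctly", {
  effects <- list(
    L_effective = list(delta = 0, theta = -0.45, alpha = -0.5, beta = -0.3,
                       gamma = -0.3),
    R_effective = list(delta = 0, theta = 0, alpha = 0, beta = -0.3,
                       gamma = -0.3),
    L_ineffective = list(delta = 0, theta = 0, alpha = -0.3, beta = -0.35,
                         gamma = -0.3),
    R_ineffective = list(delta = 0, theta = 0, alpha = 0, beta = -0.25,
                         gamma = -0.2))
  bc <- simulate_band_table(effects = effects, seed = 31)
  tab <- build_test_table(bc, simulate_outcomes())
  expect_s3_class(tab, "band_test_table")
  pick <- function(h, ctr, b) tab[tab$hemisphere == h & tab$contrast == ctr &
                                    tab$band == b, ]
  for (b in c("theta", "alpha", "beta", "gamma"))
    expect_true(pick("L", "effective", b)$significant)
  for (b in c("beta", "gamma"))
    expect_true(pick("R", "effective", b)$significant)
  for (cell in list(c("L", "delta"), c("R", "delta"), c("R", "theta"),
                    c("R", "alpha")))
    expect_false(pick(cell[1], "effective", cell[2])$significant)
  # responders only: every one-sample cell has n = 11
  expect_true(all(tab$n[tab$contrast %in% c("effective", "ineffective")] == 11))
  # paired contrast present for every hemisphere x band
  expect_equal(sum(tab$contrast == "effective_vs_ineffective"), 10)
})

test_that("a patient without left rows shrinks the left sample to n - 1", {
  effects <- list(
    L_effective = list(delta = 0, theta = -0.45, alpha = -0.5, beta = -0.3,
                       gamma = -0.3),
    R_effective = list(delta = 0, theta = 0, alpha = 0, beta = -0.3,
                       gamma = -0.3),
    L_ineffective = list(delta = 0, theta = 0, alpha = -0.3, beta = -0.35,
                         gamma = -0.3),
    R_ineffective = list(delta = 0, theta = 0, alpha = 0, beta = -0.25,
                         gamma = -0.2))
  bc <- simulate_band_table(effects = effects, seed = 32)
  # patient P03's left effective contact was an edge contact: no rows
  bc <- bc[!(bc$patient_id == "P03" & bc$hemisphere == "L" &
               bc$role == "effective"), ]
  tab <- build_test_table(bc, simulate_outcomes())
  left_eff <- tab[tab$hemisphere == "L" & tab$contrast == "effective", ]
  expect_true(all(left_eff$n == 10))
  expect_true(all(tab$n[tab$hemisphere == "R" &
                          tab$contrast == "effective"] == 11))
  expect_gte(attr(tab, "n_missing"), 5)
})

test_that("a null cohort produces (almost) no Bonferroni flags", {
  null_eff <- list(delta = 0, theta = 0, alpha = 0, beta = 0, gamma = 0)
  effects <- list(L_effective = null_eff, R_effective = null_eff,
                  L_ineffective = null_eff, R_ineffective = null_eff)
  bc <- simulate_band_table(effects = effects, seed = 33)
  tab <- build_test_table(bc, simulate_outcomes())
  expect_lte(sum(tab$significant), 2) # expected flags: 30 cells x ~0.01
})
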