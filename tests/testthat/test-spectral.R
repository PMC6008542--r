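test_that("the analysis grid and band bins match the design arithmetic", {
  g <- frequency_grid()
  expect_length(g, 200)
  expect_equal(g[1], 1)
  expect_equal(g[200], 50)
  expect_true(all(diff(g) > 0))
  # every grid frequency belongs to exactly one of the 5 bands
  edges <- scc_band_edges()
  counts <- rowSums(vapply(names(edges), function(b) {
    e <- edges[[b]]
    if (b == "gamma") g >= e[1] & g <= e[2] else g >= e[1] & g < e[2]
  }, logical(200)))
  expect_true(all(counts == 1))
})

test_that("Morlet spectrogram localizes sinusoids on the grid", {
  expect_true(all(morlet_cwt(numeric(512))$magnitudes == 0))

  t <- seq_len(60 * 128) / 128
  sp <- morlet_cwt(sin(2 * pi * 10 * t))
  avg <- rowMeans(sp$magnitudes)
  expect_lt(abs(sp$freqs[which.max(avg)] - 10), diff(sp$freqs[1:2]) + 1e-9)
  expect_lt(abs(max(avg) - 1), 0.1) # unit sine ~ unit peak modulus

  two <- morlet_cwt(sin(2 * pi * 6 * t) + sin(2 * pi * 40 * t))
  avg2 <- rowMeans(two$magnitudes)
  f <- two$freqs
  lo <- f[f < 20][which.max(avg2[f < 20])]
  hi <- f[f >= 20][which.max(avg2[f >= 20])]
  expect_lt(abs(lo - 6), 0.5)
  expect_lt(abs(hi - 40), 1)

  expect_warning(morlet_cwt(rnorm(128)), class = "scclfp_short_epoch_warning")
})

test_that("relative change is the median-difference ratio", {
  expect_equal(relative_change(c(1, 2, 3), c(4, 4, 8)), -0.5)
  v <- rlnorm(50)
  expect_equal(relative_change(v, v), 0)
  expect_equal(relative_change(2 * v, v), 1)
  expect_error(relative_change(v, numeric(3)),
               class = "scclfp_degenerate_baseline_error")
})

test_that("relative change is scale invariant", {
  set.seed(42)
  for (i in 1:100) {
    a <- rlnorm(sample(5:50, 1))
    b <- rlnorm(length(a))
    cc <- runif(1, 0.01, 100)
    expect_equal(relative_change(cc * a, cc * b), relative_change(a, b),
                 tolerance = 1e-12)
  }
})

test_that("order-statistic bootstrap medians follow the exact resampling law", {
  xs <- c(1, 3, 7, 20, 100) # sorted, odd n
  set.seed(5)
  m <- scclfp:::boot_medians_sorted(xs, 1e5)
  emp <- as.numeric(table(factor(m, levels = xs))) / 1e5
  # closed form: P(resample median <= x_(j)) = P(Binom(5, j/5) >= 3)
  cdf <- pbinom(2, 5, (1:5) / 5, lower.tail = FALSE)
  expect_equal(emp, diff(c(0, cdf)), tolerance = 0.01)

  # even n: agree with a naive resampling bootstrap in distribution
  xe <- c(0, 1, 2, 4, 8, 16)
  set.seed(6)
  fast <- scclfp:::boot_medians_sorted(xe, 4e4)
  naive <- apply(matrix(sample(xe, 6 * 4e4, replace = TRUE), nrow = 6), 2,
                 median)
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(quantile(fast, qs), quantile(naive, qs), tolerance = 0.26)
  expect_equal(mean(fast), mean(naive), tolerance = 0.05)
})

test_that("degenerate rows give exact point confidence intervals", {
  pre <- spectrogram(c(5, 10), 0:2, matrix(4, 2, 3))
  post <- spectrogram(c(5, 10), 0:2, matrix(2, 2, 3))
  fci <- bootstrap_relative_change(pre, post, n_boot = 200, seed = 1)
  expect_equal(fci$ci_min, c(-0.5, -0.5))
  expect_equal(fci$ci_mid, c(-0.5, -0.5))
  expect_equal(fci$ci_max, c(-0.5, -0.5))
})

test_that("bootstrap guards its preconditions and is seed-reproducible", {
  pre <- spectrogram(1:3, 1:50, matrix(rlnorm(150), 3))
  post <- spectrogram(1:3, 1:50, matrix(rlnorm(150), 3))
  expect_error(bootstrap_relative_change(pre, post, n_boot = 50),
               class = "scclfp_config_error")
  other <- spectrogram(2:4, 1:50, post$magnitudes)
  expect_error(bootstrap_relative_change(pre, other),
               class = "scclfp_value_error")
  a <- bootstrap_relative_change(pre, post, n_boot = 300, seed = 9)
  b <- bootstrap_relative_change(pre, post, n_boot = 300, seed = 9)
  expect_identical(a, b)
  expect_equal(a$ci_mid, (a$ci_min + a$ci_max) / 2)
})

test_that("null rows give CIs that cover zero at roughly the nominal rate", {
  set.seed(7)
  hits <- 0; mids <- numeric(100)
  for (i in 1:100) {
    pre <- spectrogram(c(5, 10), 1:500, matrix(rlnorm(1000), 2))
    post <- spectrogram(c(5, 10), 1:500, matrix(rlnorm(1000), 2))
    fci <- bootstrap_relative_change(pre, post, n_boot = 300, seed = i)
    hits <- hits + (fci$ci_min[1] <= 0 && fci$ci_max[1] >= 0)
    mids[i] <- fci$ci_mid[1]
  }
  expect_gte(hits, 88)
  expect_lt(abs(median(mids)), 0.05)
})

test_that("band aggregation averages CI midpoints over the right bins", {
  g <- frequency_grid()
  const <- structure(data.frame(freq = g, ci_min = 0.3, ci_mid = 0.3,
                                ci_max = 0.3),
                     class = c("frequency_ci", "data.frame"))
  expect_equal(unclass(band_aggregate(const))[1:5],
               c(delta = 0.3, theta = 0.3, alpha = 0.3, beta = 0.3,
                 gamma = 0.3),
               ignore_attr = TRUE)

  alpha_only <- const
  alpha_only$ci_mid <- ifelse(g >= 8 & g < 15, -0.5, 0)
  bc <- band_aggregate(alpha_only)
  expect_equal(bc[["alpha"]], -0.5)
  expect_equal(unname(unclass(bc)[c("delta", "theta", "beta", "gamma")]),
               rep(0, 4))

  ident <- const
  ident$ci_mid <- g
  bc2 <- band_aggregate(ident)
  expect_equal(bc2[["theta"]], mean(g[g >= 4 & g < 8]))
  expect_equal(bc2[["gamma"]], mean(g[g >= 30 & g <= 50]))
})

test_that("cycle analysis is deterministic and scale equivariant", {
  set.seed(8)
  pair <- structure(list(pre = rnorm(1024), post = rnorm(1024),
                         rate_hz = 128, cycle = NULL,
                         lost_fraction_pre = 0, lost_fraction_post = 0,
                         n_segments_pre = 0, n_segments_post = 0,
                         n_nominal = 2048),
                    class = "epoch_pair")
  cfg <- spectral_config(n_boot = 200, seed = 13)
  a <- analyze_cycle(pair, cfg)
  b <- analyze_cycle(pair, cfg)
  expect_identical(a, b)

  scaled <- pair
  scaled$pre <- 7.3 * pair$pre
  scaled$post <- 7.3 * pair$post
  expect_equal(as.numeric(analyze_cycle(scaled, cfg)), as.numeric(a),
               tolerance = 1e-10)
})
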