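test_that("zero-phase bandpass keeps passband amplitude and kills slow drift", {
  rate <- 1024
  t <- seq_len(60 * rate) / rate
  sine <- sin(2 * pi * 10 * t)
  out <- bandpass_zero_phase(sine, rate)
  expect_lt(abs(fft_amplitude(out, rate, 10) - 1), 0.05)

  drift <- 100 * sin(2 * pi * 0.1 * t)
  res <- bandpass_zero_phase(drift, rate)
  expect_lt(fft_amplitude(res, rate, 0.1, df = 0.05), 10)

  # zero net phase: input/output cross-correlation peaks at lag 0
  cc <- stats::ccf(out, sine, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass_zero_phase(sine, rate_hz = 80),
               class = "scclfp_nyquist_error")
})

test_that("decimation hits round(duration x 128) samples at any native rate", {
  for (fs in c(1024, 1525, 2034)) {
    x <- bandpass_zero_phase(sin(2 * pi * 10 * seq_len(60 * fs) / fs), fs)
    y <- decimate_to_rate(x, fs)
    expect_equal(length(y), 7680)
    expect_lt(abs(fft_amplitude(y, 128, 10) - 1), 0.02)
  }
  expect_error(decimate_to_rate(rnorm(100), 100, target_hz = 200),
               class = "scclfp_value_error")
})

test_that("amplitude/duration rule flags exactly the qualifying transients", {
  rate <- 1024
  x <- numeric(10 * rate)
  expect_equal(nrow(detect_artifacts(x, rate)), 0)

  x[(2 * rate):(2 * rate + 0.3 * rate)] <- 150 # 300 ms, qualifies
  x[(6 * rate):(6 * rate + 0.1 * rate)] <- -150 # 100 ms, too short
  hits <- detect_artifacts(x, rate)
  expect_equal(nrow(hits), 1)
  expect_lte(hits$start_s, 2)
  expect_gte(hits$end_s, 2.3 - 2 / rate)
})

test_that("pruning discards (not blanks) samples and reports the lost fraction", {
  rate <- 128
  x <- rnorm(60 * rate)
  clean <- prune_segments(x, rate, data.frame(start_s = numeric(),
                                              end_s = numeric()))
  expect_identical(clean$samples, x)
  expect_equal(clean$lost_fraction, 0)

  ann <- data.frame(channel = "all", start_s = c(0, 30), end_s = c(5, 35))
  pr <- prune_segments(x, rate, ann)
  expect_equal(length(pr$samples), 50 * rate)
  expect_equal(pr$lost_fraction, 1 / 6)
  # removed, not zero-filled: retained values are a subsequence of x
  expect_identical(pr$samples, x[pr$keep])

  expect_error(prune_segments(x, rate,
                              data.frame(start_s = 0, end_s = 60)),
               class = "scclfp_empty_epoch_error")
})

test_that("lost fraction is invariant to annotation order and splitting", {
  rate <- 128
  x <- rnorm(60 * rate)
  whole <- data.frame(start_s = c(3, 40), end_s = c(9, 42))
  split <- data.frame(start_s = c(40, 6, 3), end_s = c(42, 9, 6))
  expect_equal(prune_segments(x, rate, whole)$lost_fraction,
               prune_segments(x, rate, split)$lost_fraction)
  expect_identical(prune_segments(x, rate, whole)$samples,
                   prune_segments(x, rate, split)$samples)
})

test_that("differential derivation subtracts the flanking contacts", {
  rate <- 128
  n <- rate * 4
  samples <- rbind(L1 = rnorm(n), L2 = rnorm(n), L3 = rnorm(n),
                   L4 = rnorm(n), R2 = rnorm(n), R4 = rnorm(n))
  rec <- lfp_recording(samples, rate, rownames(samples))
  d <- derive_differential(rec, "L2")
  expect_equal(d$samples, unname(samples["L1", ] - samples["L3", ]))
  expect_identical(c(d$minuend, d$subtrahend), c("L1", "L3"))
  d3 <- derive_differential(rec, "R3")
  expect_equal(d3$samples, unname(samples["R2", ] - samples["R4", ]))

  # identical neighbours cancel exactly
  rec2 <- lfp_recording(rbind(L1 = samples["L1", ], L2 = rnorm(n),
                              L3 = samples["L1", ]), rate,
                        c("L1", "L2", "L3"))
  expect_true(all(derive_differential(rec2, "L2")$samples == 0))

  expect_error(derive_differential(rec, "L4"),
               class = "scclfp_no_differential_error")
  expect_error(derive_differential(rec, "R2"), # R1 missing
               class = "scclfp_no_differential_error")
})

test_that("swapping the flanking pair negates the differential", {
  rate <- 64
  n <- 256
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  fwd <- lfp_recording(rbind(L1 = a, L2 = b, L3 = c_), rate,
                       c("L1", "L2", "L3"))
  rev <- lfp_recording(rbind(L1 = c_, L2 = b, L3 = a), rate,
                       c("L1", "L2", "L3"))
  expect_equal(derive_differential(fwd, "L2")$samples,
               -derive_differential(rev, "L2")$samples)
})

test_that("annotations on either electrode of the pair invalidate its samples", {
  rate <- 128
  n <- rate * 10
  rec <- lfp_recording(matrix(rnorm(3 * n), 3), rate, c("L1", "L2", "L3"))
  d <- derive_differential(rec, "L2")
  ann <- data.frame(channel = c("L1", "L3"), start_s = c(1, 5),
                    end_s = c(2, 6))
  masked <- mask_differential(d, ann)
  t <- (seq_len(n) - 1) / rate
  expect_true(all(!masked$valid_mask[(t >= 1 & t < 2) | (t >= 5 & t < 6)]))
  expect_true(all(masked$valid_mask[t >= 2 & t < 5]))
})

test_that("epoch windows abut stimulation onset and offset", {
  rate <- 128
  n <- 400 * rate
  t <- (seq_len(n) - 1) / rate
  rec <- lfp_recording(rbind(L1 = t, L2 = numeric(n), L3 = numeric(n)),
                       rate, c("L1", "L2", "L3"))
  d <- derive_differential(rec, "L2") # samples equal the timestamps
  cyc <- list(stim_on_s = 100, stim_off_s = 280)
  pair <- extract_epoch_pair(d, cyc)
  expect_equal(length(pair$pre), 7680)
  expect_equal(length(pair$post), 7680)
  expect_equal(range(pair$pre), c(40, 100 - 1 / rate))
  expect_equal(range(pair$post), c(280, 340 - 1 / rate))

  expect_error(extract_epoch_pair(d, list(stim_on_s = 30, stim_off_s = 210)),
               class = "scclfp_epoch_bounds_error")
})
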