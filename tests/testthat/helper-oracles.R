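# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles deliberately avoid the package's own computational
# paths.

# Exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# patterns (n <= ~12).
oracle_signed_rank_p <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- grid %*% r
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Exact two-sided rank-sum-vs-zero p by enumeration of all choose(2n, n)
# group assignments.
oracle_rank_sum_p <- function(x) {
  n <- length(x)
  r <- rank(c(x, numeric(n)))
  W <- sum(r[seq_len(n)])
  combs <- utils::combn(2 * n, n)
  Ws <- apply(combs, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Dominant FFT amplitude of a real signal near frequency f0 (+/- df Hz).
fft_amplitude <- function(x, rate, f0, df = 1) {
  sp <- Mod(stats::fft(x))
  f <- (seq_along(x) - 1) / length(x) * rate
  sel <- f >= f0 - df & f <= f0 + df
  2 * max(sp[sel]) / length(x)
}

# A recording holding one sinusoid per channel.
sine_recording <- function(freqs_hz, amp = 1, rate = 1024, duration = 10,
                           labels = NULL, patient_id = "T") {
  t <- seq_len(round(duration * rate)) / rate
  samples <- do.call(rbind, lapply(freqs_hz, function(f) amp * sin(2 * pi * f * t)))
  if (is.null(labels)) labels <- contact_labels()[seq_along(freqs_hz)]
  lfp_recording(samples, rate, labels, patient_id = patient_id)
}

# Hand-crafted EDF header (optionally with data records), for reader edge
# cases the package writer never produces.
craft_edf <- function(path, labels = character(), spr = integer(),
                      n_rec = 0, rec_dur = 1, data = list(),
                      phys = c(-100, 100)) {
  ns <- length(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(formatC(substr(s, 1, w), width = -w), con,
                                  eos = NULL)
  put("0", 8); put("craft", 80); put("craft", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256 * (ns + 1)), 8); put("", 44)
  put(as.character(n_rec), 8); put(as.character(rec_dur), 8)
  put(as.character(ns), 4)
  for (l in labels) put(l, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(as.character(phys[1]), 8)
  for (i in seq_len(ns)) put(as.character(phys[2]), 8)
  for (i in seq_len(ns)) put("-32768", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(as.character(spr[i]), 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
      writeBin(as.integer(data[[i]][idx]), con, size = 2, endian = "little")
    }
  }
  path
}

# Band-change long table with a known effect layout, for group statistics
# tests that bypass the signal pipeline.
simulate_band_table <- function(n_resp = 11, n_non = 3, effects, noise_sd = 0.03,
                                seed = 1) {
  set.seed(seed)
  bands <- names(scc_band_edges())
  rows <- list()
  for (p in seq_len(n_resp + n_non)) {
    pid <- sprintf("P%02d", p)
    for (hemi in c("L", "R")) {
      for (role in c("effective", "ineffective")) {
        mu <- effects[[paste(hemi, role, sep = "_")]]
        for (b in bands) {
          val <- (if (p <= n_resp) mu[[b]] else 0) + rnorm(1, 0, noise_sd)
          rows[[length(rows) + 1]] <- data.frame(
            patient_id = pid, hemisphere = hemi, role = role, band = b,
            value = val)
        }
      }
    }
  }
  do.call(rbind, rows)
}

simulate_outcomes <- function(n_resp = 11, n_non = 3) {
  n <- n_resp + n_non
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             baseline_hdrs17 = rep(24, n),
             month6_hdrs17 = c(rep(8, n_resp), rep(20, n_non)),
             responder_6mo = c(rep(TRUE, n_resp), rep(FALSE, n_non)),
             time_to_stable_weeks = c(seq_len(n_resp) + 3, rep(NA, n_non)))
}
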