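# Exact nonparametric inference on band-change samples. Sample sizes here
# are ~10-14 per contrast, so exact null distributions (full enumeration,
# computed by generating-function / subset-sum convolution) replace normal
# approximations throughout; mid-ranks handle ties.

test_result <- function(W, p, n, g, method) {
  structure(list(statistic_W = W, p_two_sided = p, n = n, g = g,
                 method = method),
            class = "scclfp_test")
}

#' @export
print.scclfp_test <- function(x, ...) {
  cat(sprintf("<%s> n = %d, W = %.4g, p = %.4g, g = %.4g\n",
              x$method, x$n, x$statistic_W, x$p_two_sided,
              if (is.na(x$g)) NA else x$g))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov non-gaussianity check
#'
#' KS test of the sample against a normal with the sample mean and SD.
#' Advisory only: the pipeline always uses rank tests; this merely
#' documents that the band-change values are non-gaussian.
#'
#' @param x Numeric sample, n >= 4.
#' @return p-value (`NA` for a constant sample).
#' @export
ks_nongaussianity <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4)
    scc_abort("scclfp_insufficient_data_error",
              "need at least 4 observations for the KS check")
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s)$p.value)
}

# Exact null distribution of 2*W for the signed-rank test, where r2 are the
# doubled mid-ranks (integers): counts over all 2^n sign assignments via
# polynomial convolution. Doubles are exact up to 2^53 >> 2^n at our sizes.
signed_rank_counts <- function(r2) {
  S <- sum(r2)
  cnt <- numeric(S + 1)
  cnt[1] <- 1
  for (v in r2) {
    shifted <- c(numeric(v), cnt[seq_len(S + 1 - v)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Exact two-tailed Wilcoxon signed-rank test
#'
#' One-sample test of symmetry about `mu` (or a paired test when applied to
#' differences). Zeros are dropped, tied absolute values receive mid-ranks,
#' and the two-sided p-value is exact over all `2^n` sign assignments
#' (computed by generating-function convolution, identical to full
#' enumeration): `p = min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x Numeric sample.
#' @param mu Null center (default 0).
#' @return An `scclfp_test` with the positive-rank sum `W`, exact `p`,
#'   effective `n` and one-sample Hedges' g.
#' @export
signed_rank_exact <- function(x, mu = 0) {
  d <- x[is.finite(x)] - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    scc_abort("scclfp_all_zero_error",
              "all observations equal the null value; test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  cnt <- signed_rank_counts(r2)
  w2 <- as.integer(round(2 * W))
  tot <- 2^n
  p_le <- sum(cnt[seq_len(w2 + 1)]) / tot
  p_ge <- sum(cnt[(w2 + 1):length(cnt)]) / tot
  p <- min(1, 2 * min(p_le, p_ge))
  g <- if (length(x) >= 2 && stats::sd(x) > 0) hedges_g(x, mu) else NA_real_
  test_result(W, p, n, g, "signed_rank")
}

# Counts of size-m subsets of `vals` (integers) by subset sum: dynamic
# programme over items; f[k+1, s+1] = number of k-subsets summing to s.
subset_sum_counts <- function(vals, m) {
  S <- sum(vals)
  f <- matrix(0, nrow = m + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (v in vals) {
    for (k in seq(min(m, nrow(f) - 1), 1)) {
      shifted <- c(numeric(v), f[k, seq_len(S + 1 - v)])
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  f[m + 1, ]
}

#' Exact two-tailed rank-sum test of a sample against zero
#'
#' Two-sample Wilcoxon-Mann-Whitney rank-sum test of `x` against an
#' equal-length all-zero pseudo-sample, with mid-ranks for the massive tie
#' at zero. Provided because the one-sample-versus-zero question can also
#' be posed as a rank-sum contrast; [signed_rank_exact()] is the pipeline
#' default. The p-value is exact over all `choose(2n, n)` group assignments
#' (subset-sum enumeration) up to a combined size of 60, beyond which the
#' tie-corrected normal approximation of [stats::wilcox.test()] is used.
#'
#' @param x Numeric sample.
#' @return An `scclfp_test` with the rank sum of `x` as `W`.
#' @export
rank_sum_vs_zero_exact <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0)
    scc_abort("scclfp_value_error", "empty sample")
  combined <- c(x, numeric(n))
  r <- rank(combined)
  W <- sum(r[seq_len(n)])
  if (2 * n <= 60) {
    r2 <- as.integer(round(2 * r))
    cnt <- subset_sum_counts(r2, n)
    tot <- choose(2 * n, n)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(cnt[seq_len(w2 + 1)]) / tot
    p_ge <- sum(cnt[(w2 + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, numeric(n), exact = FALSE)$p.value)
  }
  g <- if (n >= 2 && stats::sd(x) > 0) hedges_g(x) else NA_real_
  test_result(W, p, n, g, "rank_sum_vs_zero")
}

#' Hedges' g effect size
#'
#' One-sample standardized mean difference with the small-sample bias
#' correction `J = 1 - 3 / (4n - 5)`:
#' `g = J * (mean(x) - mu) / sd(x)`.
#'
#' @param x Numeric sample, n >= 2, sd > 0.
#' @param mu Null center (default 0).
#' @return Hedges' g.
#' @export
hedges_g <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2)
    scc_abort("scclfp_insufficient_data_error", "need n >= 2 for Hedges' g")
  s <- stats::sd(x)
  if (s == 0)
    scc_abort("scclfp_degenerate_sample_error",
              "zero standard deviation; effect size undefined")
  (1 - 3 / (4 * n - 5)) * (mean(x) - mu) / s
}

#' @rdname hedges_g
#' @param y Paired sample; the paired g applies the one-sample formula to
#'   `x - y`.
#' @export
hedges_g_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  hedges_g(x - y)
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m` for a family of `m` comparisons (five frequency bands per
#' contrast in this pipeline: 0.05 / 5 = 0.01).
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Family size (default 5).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 5) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Correlate band changes with time to stable clinical response
#'
#' Both Pearson and Spearman coefficients are reported (with their
#' two-sided p-values) since either is defensible for an n ~ 11 sample.
#' Pairs with a missing time are excluded.
#'
#' @param band_changes Numeric vector of per-patient band-change values.
#' @param times_to_response Numeric vector of weeks (NA allowed), same
#'   length.
#' @return List with `pearson` (`r`, `p`), `spearman` (`rho`, `p`) and `n`.
#' @export
correlate_with_outcome <- function(band_changes, times_to_response) {
  stopifnot(length(band_changes) == length(times_to_response))
  ok <- is.finite(band_changes) & is.finite(times_to_response)
  x <- band_changes[ok]
  y <- times_to_response[ok]
  if (length(x) < 4)
    scc_abort("scclfp_insufficient_data_error",
              "need at least 4 complete pairs for the outcome correlation")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(pearson = list(r = unname(pe$estimate), p = pe$p.value),
       spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       n = length(x))
}

#' Group-level band test table
#'
#' Builds the full inferential table from per-cycle band changes: one
#' one-sample test against zero per (hemisphere, role, band) and one paired
#' effective-vs-ineffective test per (hemisphere, band), restricted to
#' 6-month responders, with Bonferroni flags at `alpha / 5`. Patients
#' lacking a value for a cell (e.g. an edge effective contact with no
#' differential) are simply absent from that cell's sample; the attribute
#' `n_missing` counts them.
#'
#' @param band_changes Long data.frame with columns `patient_id`,
#'   `hemisphere`, `role`, `band`, `value` (one row per patient x cycle x
#'   band).
#' @param outcomes data.frame from [patient_outcomes()] (needs
#'   `patient_id`, `responder_6mo`).
#' @param alpha Family-wise level, default 0.05 (threshold `alpha/5`).
#' @param method One-sample test: `"signed_rank"` (default) or
#'   `"rank_sum_vs_zero"`.
#' @param responders_only Restrict to responders (default TRUE).
#' @return data.frame of class `band_test_table` with columns `hemisphere`,
#'   `contrast`, `band`, `n`, `W`, `p`, `g`, `significant`.
#' @export
build_test_table <- function(band_changes, outcomes, alpha = 0.05,
                             method = c("signed_rank", "rank_sum_vs_zero"),
                             responders_only = TRUE) {
  method <- match.arg(method)
  bands <- names(scc_band_edges())
  df <- band_changes
  responders <- outcomes$patient_id[outcomes$responder_6mo]
  if (responders_only) df <- df[df$patient_id %in% responders, , drop = FALSE]
  thr <- bonferroni_threshold(alpha, length(bands))
  one_sample <- if (method == "signed_rank") signed_rank_exact
                else rank_sum_vs_zero_exact
  rows <- list()
  n_missing <- 0L
  add <- function(hemi, contrast, band, x) {
    res <- tryCatch(
      if (contrast == "effective_vs_ineffective") signed_rank_exact(x)
      else one_sample(x),
      scclfp_error = function(e) NULL)
    if (is.null(res)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      hemisphere = hemi, contrast = contrast, band = band,
      n = res$n, W = res$statistic_W, p = res$p_two_sided,
      g = if (is.null(res$g)) NA_real_ else res$g,
      significant = res$p_two_sided < thr)
  }
  n_expected <- length(unique(df$patient_id))
  for (hemi in c("L", "R")) {
    for (role in c("effective", "ineffective")) {
      sub <- df[df$hemisphere == hemi & df$role == role, , drop = FALSE]
      for (b in bands) {
        x <- sub$value[sub$band == b]
        n_missing <- n_missing + (n_expected - length(x))
        if (length(x)) add(hemi, role, b, x)
      }
    }
    eff <- df[df$hemisphere == hemi & df$role == "effective", , drop = FALSE]
    ine <- df[df$hemisphere == hemi & df$role == "ineffective", , drop = FALSE]
    for (b in bands) {
      e <- eff[eff$band == b, c("patient_id", "value")]
      i <- ine[ine$band == b, c("patient_id", "value")]
      m <- merge(e, i, by = "patient_id")
      if (nrow(m)) add(hemi, "effective_vs_ineffective", b,
                       m$value.x - m$value.y)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "family_size") <- length(bands)
  attr(out, "threshold") <- thr
  attr(out, "method") <- method
  attr(out, "n_missing") <- n_missing
  class(out) <- c("band_test_table", "data.frame")
  out
}
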