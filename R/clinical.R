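# Clinical outcome definitions: the 50% HDRS17 response rule, time to
# stable response, and cohort summary statistics.

#' Classify 6-month antidepressant response
#'
#' Response is a decrease of at least 50% from the baseline 17-item
#' Hamilton Depression Rating Scale score: responder iff
#' `(baseline - followup) / baseline >= 0.5` (the boundary counts).
#' Vectorized.
#'
#' @param baseline,followup HDRS17 scores in \[0, 52\].
#' @return Logical vector.
#' @export
classify_response <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(!is.finite(followup)) ||
      any(baseline < 0 | baseline > 52) || any(followup < 0 | followup > 52))
    scc_abort("scclfp_schema_error", "HDRS17 scores must lie in [0, 52]")
  if (any(baseline == 0))
    scc_abort("scclfp_undefined_baseline_error",
              "response undefined for a zero baseline score")
  (baseline - followup) / baseline >= 0.5
}

#' Time to stable clinical response
#'
#' The first week `w` such that weeks `w`, `w+1`, `w+2` all meet the 50%
#' decrease rule relative to baseline; `NA` if no such 3-week run exists
#' (including series shorter than 3 weeks).
#'
#' @param weekly_series Numeric HDRS17 scores for consecutive weeks
#'   starting at week 1.
#' @param baseline Baseline HDRS17 score.
#' @return Week number (integer) or `NA`.
#' @export
time_to_stable_response <- function(weekly_series, baseline) {
  if (length(weekly_series) < 3) return(NA_real_)
  ok <- classify_response(rep(baseline, length(weekly_series)), weekly_series)
  runs <- ok & c(ok[-1], FALSE) & c(ok[-(1:2)], FALSE, FALSE)
  w <- which(runs)
  if (length(w)) as.numeric(w[1]) else NA_real_
}

#' Cohort clinical summary
#'
#' Column means and sample (n-1) standard deviations of baseline, 6-month
#' and time-to-stable-response scores (NA excluded), the responder count
#' under [classify_response()], and the same statistics rounded to the
#' reporting precision of one decimal place.
#'
#' @param outcomes data.frame with `baseline_hdrs17`, `month6_hdrs17` and
#'   `time_to_stable_weeks` (e.g. from [patient_outcomes()]).
#' @return List with `n`, `n_responders`, and per-column `mean`/`sd`
#'   (exact) plus `rounded` (1 d.p.).
#' @export
cohort_summary <- function(outcomes) {
  col_stats <- function(v) {
    v <- v[is.finite(v)]
    list(n = length(v), mean = mean(v),
         sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  }
  cols <- list(baseline = col_stats(outcomes$baseline_hdrs17),
               month6 = col_stats(outcomes$month6_hdrs17),
               time_to_stable = col_stats(outcomes$time_to_stable_weeks))
  resp <- classify_response(outcomes$baseline_hdrs17, outcomes$month6_hdrs17)
  list(n = nrow(outcomes),
       n_responders = sum(resp),
       columns = cols,
       rounded = lapply(cols, function(s)
         list(mean = round(s$mean, 1), sd = round(s$sd, 1))))
}

#' Reference TRD cohort clinical scores
#'
#' The published clinical characteristics of the 14-patient
#' treatment-resistant depression cohort this pipeline was designed around:
#' baseline and 6-month HDRS17 scores and time to stable response in weeks
#' (NA for the persistent non-responder). Shipped as a plain CSV fixture.
#'
#' @return data.frame with one row per patient.
#' @export
trd_cohort_clinical <- function() {
  path <- system.file("extdata", "trd_cohort_clinical.csv",
                      package = "scclfp", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$time_to_stable_weeks <- as.numeric(df$time_to_stable_weeks)
  df
}
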