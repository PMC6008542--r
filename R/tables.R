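# Sidecar CSV tables driving the pipeline: artifact annotations, stimulation
# cycle metadata, and clinical scores. All times are seconds from recording
# start; all intervals are half-open [start_s, end_s).

#' Read an artifact annotation table
#'
#' Expects a CSV with header `channel,start_s,end_s` and optionally a
#' `patient_id` column (cohort datasets annotate several recordings in one
#' file; a missing column means the rows apply to every patient). A channel
#' of `"all"` applies to every channel. Overlapping or abutting intervals on
#' the same (patient, channel) are merged.
#'
#' @param path CSV file path.
#' @return data.frame with columns `patient_id`, `channel`, `start_s`,
#'   `end_s`, sorted by start time.
#' @export
read_artifact_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "start_s", "end_s")
  if (!all(need %in% names(df)))
    scc_abort("scclfp_schema_error",
              "artifact table must have columns channel,start_s,end_s")
  if (nrow(df) == 0)
    return(data.frame(patient_id = character(), channel = character(),
                      start_s = numeric(), end_s = numeric()))
  if (is.null(df$patient_id)) df$patient_id <- ""
  df$start_s <- as.numeric(df$start_s)
  df$end_s <- as.numeric(df$end_s)
  if (anyNA(df$start_s) || anyNA(df$end_s))
    scc_abort("scclfp_schema_error", "non-numeric artifact timestamps")
  if (any(df$start_s < 0) || any(df$end_s <= df$start_s))
    scc_abort("scclfp_schema_error",
              "artifact intervals need 0 <= start_s < end_s")
  chan <- tolower(trimws(df$channel))
  canon <- canonical_contact(df$channel)
  bad <- chan != "all" & is.na(canon)
  if (any(bad))
    scc_abort("scclfp_schema_error",
              sprintf("unknown artifact channel label(s): %s",
                      paste(unique(df$channel[bad]), collapse = ", ")))
  df$channel <- ifelse(chan == "all", "all", canon)
  merge_annotations(df[c("patient_id", "channel", "start_s", "end_s")])
}

#' Merge overlapping annotation intervals
#'
#' Union of half-open intervals per (patient, channel); abutting intervals
#' are coalesced. Idempotent and independent of row order.
#'
#' @param annotations data.frame with `channel`, `start_s`, `end_s` and
#'   optionally `patient_id`.
#' @return data.frame of disjoint intervals.
#' @export
merge_annotations <- function(annotations) {
  df <- as.data.frame(annotations)
  if (is.null(df$patient_id)) df$patient_id <- ""
  if (nrow(df) == 0) return(df)
  key <- paste(df$patient_id, df$channel, sep = "\r")
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$start_s, g$end_s), ]
    starts <- g$start_s[1]; ends <- g$end_s[1]
    for (i in seq_len(nrow(g))[-1]) {
      j <- length(ends)
      if (g$start_s[i] <= ends[j]) {
        ends[j] <- max(ends[j], g$end_s[i])
      } else {
        starts <- c(starts, g$start_s[i])
        ends <- c(ends, g$end_s[i])
      }
    }
    data.frame(patient_id = g$patient_id[1], channel = g$channel[1],
               start_s = starts, end_s = ends)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$patient_id, out$channel, out$start_s), ]
}

#' Read the stimulation-cycle metadata table
#'
#' CSV schema: `patient_id,stim_contact,hemisphere,role,stim_on_s,stim_off_s`.
#' One row per stimulation cycle (nominally 1 min pre, 3 min stimulation,
#' 1 min post). Roles are `effective`, `ineffective` or `sham` and are known
#' only retrospectively from 6-month clinical outcomes.
#'
#' @param path CSV file path.
#' @return Validated data.frame of cycles.
#' @export
read_cycle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "stim_contact", "hemisphere", "role",
            "stim_on_s", "stim_off_s")
  if (!all(need %in% names(df)))
    scc_abort("scclfp_schema_error",
              paste("cycle table must have columns",
                    paste(need, collapse = ",")))
  canon <- canonical_contact(df$stim_contact)
  if (anyNA(canon))
    scc_abort("scclfp_schema_error",
              sprintf("unknown stim contact label(s): %s",
                      paste(unique(df$stim_contact[is.na(canon)]),
                            collapse = ", ")))
  df$stim_contact <- canon
  df$hemisphere <- toupper(trimws(df$hemisphere))
  if (!all(df$hemisphere %in% c("L", "R")))
    scc_abort("scclfp_schema_error", "hemisphere must be L or R")
  if (!all(df$hemisphere == substr(df$stim_contact, 1, 1)))
    scc_abort("scclfp_schema_error",
              "hemisphere does not match stim contact label")
  df$role <- tolower(trimws(df$role))
  if (!all(df$role %in% c("effective", "ineffective", "sham")))
    scc_abort("scclfp_schema_error",
              "role must be effective, ineffective or sham")
  df$stim_on_s <- as.numeric(df$stim_on_s)
  df$stim_off_s <- as.numeric(df$stim_off_s)
  if (anyNA(df$stim_on_s) || anyNA(df$stim_off_s) ||
      any(df$stim_on_s < 0) || any(df$stim_off_s <= df$stim_on_s))
    scc_abort("scclfp_schema_error", "invalid stimulation on/off times")
  if (anyDuplicated(df[c("patient_id", "stim_contact")]))
    scc_abort("scclfp_duplicate_cycle_error",
              "duplicate (patient, contact) cycle rows")
  df
}

#' Read the clinical outcomes table
#'
#' CSV schema: `patient_id,baseline_hdrs17,month6_hdrs17` plus optional
#' `weekly_hdrs17` (semicolon-joined weekly HDRS17 series starting at week
#' 1) and optional `time_to_stable_weeks`. HDRS17 scores must lie in
#' \[0, 52\].
#'
#' @param path CSV file path.
#' @return data.frame with a `weekly_hdrs17` list column (`NULL` entries
#'   where the series is unavailable).
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "baseline_hdrs17", "month6_hdrs17")
  if (!all(need %in% names(df)))
    scc_abort("scclfp_schema_error",
              "clinical table must have columns patient_id,baseline_hdrs17,month6_hdrs17")
  for (col in c("baseline_hdrs17", "month6_hdrs17")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]) || any(df[[col]] < 0 | df[[col]] > 52))
      scc_abort("scclfp_schema_error",
                sprintf("%s scores must be numeric in [0, 52]", col))
  }
  if (!is.null(df$weekly_hdrs17)) {
    df$weekly_hdrs17 <- lapply(as.character(df$weekly_hdrs17), function(s) {
      s <- trimws(s)
      if (is.na(s) || s == "") return(NULL)
      v <- suppressWarnings(as.numeric(strsplit(s, ";", fixed = TRUE)[[1]]))
      if (anyNA(v) || any(v < 0 | v > 52))
        scc_abort("scclfp_schema_error", "malformed weekly_hdrs17 series")
      v
    })
  } else {
    df$weekly_hdrs17 <- vector("list", nrow(df))
  }
  if (!is.null(df$time_to_stable_weeks))
    df$time_to_stable_weeks <- suppressWarnings(as.numeric(df$time_to_stable_weeks))
  df
}

#' Derive patient outcomes from a clinical table
#'
#' Applies the 50%-decrease response rule at 6 months and determines time to
#' stable response (first week opening 3 consecutive weeks at a 50% HDRS17
#' decrease) from the weekly series where available, otherwise from a
#' provided `time_to_stable_weeks` column, otherwise `NA`.
#'
#' @param clinical data.frame from [read_clinical_table()].
#' @return data.frame with `patient_id`, `baseline_hdrs17`,
#'   `month6_hdrs17`, `responder_6mo`, `time_to_stable_weeks`.
#' @export
patient_outcomes <- function(clinical) {
  resp <- classify_response(clinical$baseline_hdrs17, clinical$month6_hdrs17)
  tts <- vapply(seq_len(nrow(clinical)), function(i) {
    wk <- clinical$weekly_hdrs17[[i]]
    if (!is.null(wk) && length(wk))
      return(time_to_stable_response(wk, clinical$baseline_hdrs17[i]))
    if (!is.null(clinical$time_to_stable_weeks))
      return(clinical$time_to_stable_weeks[i])
    NA_real_
  }, 0)
  data.frame(patient_id = clinical$patient_id,
             baseline_hdrs17 = clinical$baseline_hdrs17,
             month6_hdrs17 = clinical$month6_hdrs17,
             responder_6mo = resp,
             time_to_stable_weeks = tts)
}
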