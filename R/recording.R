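#' Canonical DBS contact labels
#'
#' The two quadripolar leads are labelled ventral to dorsal `L1`--`L4`
#' (left hemisphere) and `R1`--`R4` (right hemisphere).
#'
#' @return Character vector of the eight canonical labels.
#' @export
contact_labels <- function() {
  c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "R4")
}

# Map arbitrary channel label spellings ("eeg l2", "R-3", "LFP R4") onto the
# canonical L1..R4 nomenclature; unrecognizable labels come back as NA.
canonical_contact <- function(labels) {
  lab <- toupper(trimws(as.character(labels)))
  lab <- sub("^(EEG|LFP)[ _-]*", "", lab)
  lab <- gsub("[ _-]", "", lab)
  ifelse(grepl("^[LR][1-4]$", lab), lab, NA_character_)
}

#' Multi-channel referential LFP recording
#'
#' Container for a referential (common-reference) LFP signal matrix in
#' microvolts, with one row per electrode contact.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel labels, one per
#'   row of `samples`; labels recognizable as contacts are canonicalized to
#'   `L1..R4`, others are preserved verbatim.
#' @param patient_id Patient identifier string.
#' @param start_time Offset in seconds of the first sample (0 at record
#'   start).
#'
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, rate_hz, channel_labels,
                          patient_id = "", start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0)
    scc_abort("scclfp_value_error", "rate_hz must be a single positive number")
  if (length(channel_labels) != nrow(samples))
    scc_abort("scclfp_value_error",
              "channel_labels must have one entry per channel")
  canon <- canonical_contact(channel_labels)
  labels <- ifelse(is.na(canon), as.character(channel_labels), canon)
  if (anyDuplicated(labels))
    scc_abort("scclfp_value_error", "channel labels must be unique")
  rownames(samples) <- labels
  structure(
    list(patient_id = patient_id, channel_labels = labels,
         rate_hz = rate_hz, samples = samples, start_time = start_time),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> patient '%s': %d channels (%s), %.6g Hz, %.1f s\n",
    x$patient_id, nrow(x$samples),
    paste(x$channel_labels, collapse = ","), x$rate_hz,
    ncol(x$samples) / x$rate_hz))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$samples)

duration_s <- function(rec) ncol(rec$samples) / rec$rate_hz
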