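# Signal conditioning. The pipeline order is fixed: zero-phase bandpass on
# the native-rate referential signals, decimation to the 128 Hz analysis
# rate, discard-style artifact pruning, bipolar differential derivation,
# then epoch extraction.

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), so the net phase shift is zero and the effective
#' attenuation is that of an 8th-order filter.
#'
#' @param x Numeric signal vector (microvolts).
#' @param rate_hz Sampling rate of `x`.
#' @param low_hz,high_hz Passband edges in Hz (defaults 1 and 50).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, rate_hz, low_hz = 1, high_hz = 50) {
  if (rate_hz <= 2 * high_hz)
    scc_abort("scclfp_nyquist_error",
              sprintf("rate %.6g Hz cannot represent a %.6g Hz passband edge",
                      rate_hz, high_hz))
  stopifnot(low_hz > 0, high_hz > low_hz)
  bf <- signal::butter(2, c(low_hz, high_hz) / (rate_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Exact Fourier resampling of a band-limited signal to n_out samples:
# truncate (or zero-pad) the spectrum and invert. Amplitude-exact for
# content below both Nyquist rates; only the first/last few samples see
# edge ringing from the implicit periodic extension.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(as.numeric(x))
  X <- stats::fft(x)
  m <- min(n, n_out)
  Y <- complex(length.out = n_out)
  kpos <- seq_len(floor((m - 1) / 2) + 1) # DC + positive frequencies
  Y[kpos] <- X[kpos]
  kneg <- kpos[-1]
  Y[n_out + 2 - kneg] <- X[n + 2 - kneg]
  if (m %% 2 == 0) Y[m / 2 + 1] <- Re(X[m / 2 + 1])
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Decimate a band-limited signal to the analysis rate
#'
#' Assumes the input is already band-limited below `target_hz / 2` (run
#' after [bandpass_zero_phase()]). Integer rate ratios are decimated by
#' plain stride selection (the anti-alias filter already having been
#' applied); non-integer ratios (e.g. 1525 to 128 Hz) use exact Fourier
#' resampling, so the realized rate matches the target to better than
#' 1e-6 relative.
#'
#' @param x Numeric signal vector.
#' @param rate_hz Input sampling rate.
#' @param target_hz Output rate, default 128.
#' @return Signal at `target_hz`; length is `round(duration * target_hz)`.
#' @export
decimate_to_rate <- function(x, rate_hz, target_hz = 128) {
  if (target_hz > rate_hz)
    scc_abort("scclfp_value_error", "target rate exceeds source rate")
  if (target_hz == rate_hz) return(as.numeric(x))
  n_out <- round(length(x) * target_hz / rate_hz)
  ratio <- rate_hz / target_hz
  if (abs(ratio - round(ratio)) < 1e-9) {
    y <- x[seq(1, length(x), by = round(ratio))]
    length(y) <- n_out
    y[is.na(y)] <- 0
    y
  } else {
    fft_resample(x, n_out)
  }
}

#' Threshold-based artifact detector
#'
#' Flags maximal runs where `|x|` exceeds `amp_uV` for at least
#' `min_dur_ms`. This is a QC/synthetic-data helper mirroring the manual
#' annotation rule; curated annotation tables remain authoritative for
#' analysis.
#'
#' @param x Calibrated signal in microvolts.
#' @param rate_hz Sampling rate.
#' @param amp_uV Amplitude threshold (default 100).
#' @param min_dur_ms Minimum duration in milliseconds (default 250).
#' @param channel Channel label recorded in the annotations.
#' @return data.frame of annotations (`channel`, `start_s`, `end_s`),
#'   possibly empty.
#' @export
detect_artifacts <- function(x, rate_hz, amp_uV = 100, min_dur_ms = 250,
                             channel = "all") {
  over <- abs(x) > amp_uV
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / rate_hz * 1000 >= min_dur_ms)
  data.frame(channel = rep(channel, sum(keep)),
             start_s = (starts[keep] - 1) / rate_hz,
             end_s = ends[keep] / rate_hz)
}

# Logical keep-mask for n samples at rate_hz starting at t0: FALSE inside
# any half-open [start_s, end_s) annotation that applies to `channels`.
artifact_keep_mask <- function(n, rate_hz, annotations, t0 = 0,
                               channels = "all", patient_id = NULL) {
  keep <- rep(TRUE, n)
  if (is.null(annotations) || nrow(annotations) == 0) return(keep)
  ann <- annotations
  if (!is.null(ann$patient_id) && !is.null(patient_id))
    ann <- ann[ann$patient_id == "" | ann$patient_id == patient_id, ,
               drop = FALSE]
  ann <- ann[ann$channel == "all" | ann$channel %in% channels, , drop = FALSE]
  if (nrow(ann) == 0) return(keep)
  t <- t0 + (seq_len(n) - 1) / rate_hz
  for (i in seq_len(nrow(ann)))
    keep[t >= ann$start_s[i] & t < ann$end_s[i]] <- FALSE
  keep
}

#' Prune annotated artifact segments from a signal
#'
#' Samples whose timestamps fall inside any annotation are discarded (the
#' retained samples are concatenated), never zero-filled, so artifact
#' energy cannot leak into spectral estimates.
#'
#' @param x Signal vector.
#' @param rate_hz Sampling rate.
#' @param annotations data.frame with `start_s`, `end_s` (and optionally
#'   `channel`; see `channels`).
#' @param t0 Timestamp of the first sample, seconds.
#' @param channels Channel labels of `x`; annotations on any of them, or on
#'   `"all"`, apply.
#' @return List with `samples` (pruned vector), `lost_fraction`
#'   (removed / total) and `keep` (the logical mask used).
#' @export
prune_segments <- function(x, rate_hz, annotations, t0 = 0,
                           channels = "all") {
  ann <- as.data.frame(annotations)
  if (nrow(ann) && is.null(ann$channel)) ann$channel <- "all"
  keep <- artifact_keep_mask(length(x), rate_hz, ann, t0 = t0,
                             channels = channels)
  if (!any(keep))
    scc_abort("scclfp_empty_epoch_error",
              "all samples fall inside artifact annotations")
  list(samples = x[keep], lost_fraction = mean(!keep), keep = keep)
}

#' Derive a bipolar differential signal around a contact of interest
#'
#' The differential for center contact `c` is the lower flanking contact
#' minus the upper one (e.g. center `L2` gives `L1 - L3`), cancelling the
#' common reference and common-mode noise. Edge contacts (`L1`, `L4`, `R1`,
#' `R4`) have only one neighbour and admit no differential.
#'
#' @param recording An [lfp_recording] (any rate; the pipeline calls this
#'   after decimation to 128 Hz).
#' @param center_contact Canonical contact label, one of `L2,L3,R2,R3`.
#' @return An object of class `differential_signal` with fields
#'   `center_contact`, `minuend`, `subtrahend`, `rate_hz`, `samples`,
#'   `valid_mask` and `start_time`.
#' @export
derive_differential <- function(recording, center_contact) {
  stopifnot(inherits(recording, "lfp_recording"))
  center <- canonical_contact(center_contact)
  if (is.na(center))
    scc_abort("scclfp_schema_error",
              sprintf("unrecognizable contact label '%s'", center_contact))
  hemi <- substr(center, 1, 1)
  k <- as.integer(substr(center, 2, 2))
  if (k %in% c(1L, 4L))
    scc_abort("scclfp_no_differential_error",
              sprintf("edge contact %s has only one neighbour; no differential exists",
                      center))
  lower <- paste0(hemi, k - 1)
  upper <- paste0(hemi, k + 1)
  if (!all(c(lower, upper) %in% recording$channel_labels))
    scc_abort("scclfp_no_differential_error",
              sprintf("flanking contacts %s and %s not both present", lower, upper))
  samples <- recording$samples[lower, ] - recording$samples[upper, ]
  structure(
    list(center_contact = center, minuend = lower, subtrahend = upper,
         rate_hz = recording$rate_hz, samples = as.numeric(samples),
         valid_mask = rep(TRUE, length(samples)),
         start_time = recording$start_time),
    class = "differential_signal")
}

#' @export
print.differential_signal <- function(x, ...) {
  cat(sprintf("<differential_signal> %s = %s - %s, %.6g Hz, %d samples (%.2f%% pruned)\n",
              x$center_contact, x$minuend, x$subtrahend, x$rate_hz,
              length(x$samples), 100 * mean(!x$valid_mask)))
  invisible(x)
}

#' Apply artifact annotations to a differential signal
#'
#' A bipolar sample is corrupt if either electrode of the pair is, so
#' annotations on the minuend, the subtrahend, the center contact or
#' `"all"` invalidate the corresponding samples. The optional `guard_s`
#' widens every annotation symmetrically; it defaults to 0 (plain
#' discard-and-concatenate).
#'
#' @param diff_signal A `differential_signal`.
#' @param annotations Annotation data.frame.
#' @param patient_id Restrict annotations carrying a patient id.
#' @param guard_s Seconds to drop around each annotation (default 0).
#' @return The differential signal with an updated `valid_mask`.
#' @export
mask_differential <- function(diff_signal, annotations, patient_id = NULL,
                              guard_s = 0) {
  ann <- as.data.frame(annotations)
  if (nrow(ann) && guard_s > 0) {
    ann$start_s <- pmax(0, ann$start_s - guard_s)
    ann$end_s <- ann$end_s + guard_s
  }
  chans <- c(diff_signal$minuend, diff_signal$subtrahend,
             diff_signal$center_contact)
  keep <- artifact_keep_mask(length(diff_signal$samples),
                             diff_signal$rate_hz, ann,
                             t0 = diff_signal$start_time,
                             channels = chans, patient_id = patient_id)
  diff_signal$valid_mask <- diff_signal$valid_mask & keep
  diff_signal
}

#' Extract the pre/post epoch pair for one stimulation cycle
#'
#' The PRE epoch is the minute abutting stimulation onset,
#' `[stim_on - 60, stim_on)`; the POST epoch is the minute from stimulation
#' offset, `[stim_off, stim_off + 60)`. Samples flagged invalid by pruning
#' are dropped from each epoch, so the retained lengths may differ.
#'
#' @param diff_signal A `differential_signal` at the analysis rate.
#' @param cycle One-row data.frame (or list) with `stim_on_s`, `stim_off_s`
#'   and identifying metadata.
#' @param epoch_s Epoch duration in seconds (60).
#' @return An object of class `epoch_pair` with pruned `pre` and `post`
#'   sample vectors, `lost_fraction_pre/post` and the `cycle` metadata.
#' @export
extract_epoch_pair <- function(diff_signal, cycle, epoch_s = 60) {
  fs <- diff_signal$rate_hz
  t0 <- diff_signal$start_time
  n <- length(diff_signal$samples)
  t_end <- t0 + n / fs
  a_pre <- cycle$stim_on_s - epoch_s
  b_post <- cycle$stim_off_s + epoch_s
  if (a_pre < t0 - 1e-9 || b_post > t_end + 1e-9)
    scc_abort("scclfp_epoch_bounds_error",
              sprintf("recording [%.6g, %.6g) s does not cover epochs [%.6g, %.6g) s",
                      t0, t_end, a_pre, b_post))
  t <- t0 + (seq_len(n) - 1) / fs
  window <- function(a, b) {
    idx <- which(t >= a - 1e-9 & t < b - 1e-9)
    valid <- diff_signal$valid_mask[idx]
    if (!any(valid))
      scc_abort("scclfp_empty_epoch_error",
                "every sample of an epoch was pruned as artifact")
    r <- rle(valid)
    list(samples = diff_signal$samples[idx][valid],
         lost_fraction = mean(!valid), n_nominal = length(idx),
         n_segments = sum(!r$values))
  }
  pre <- window(a_pre, cycle$stim_on_s)
  post <- window(cycle$stim_off_s, b_post)
  structure(
    list(pre = pre$samples, post = post$samples,
         rate_hz = fs, cycle = cycle,
         lost_fraction_pre = pre$lost_fraction,
         lost_fraction_post = post$lost_fraction,
         n_segments_pre = pre$n_segments,
         n_segments_post = post$n_segments,
         n_nominal = pre$n_nominal + post$n_nominal),
    class = "epoch_pair")
}

#' @export
print.epoch_pair <- function(x, ...) {
  cat(sprintf("<epoch_pair> pre %d / post %d samples @ %g Hz (lost %.1f%% / %.1f%%)\n",
              length(x$pre), length(x$post), x$rate_hz,
              100 * x$lost_fraction_pre, 100 * x$lost_fraction_post))
  invisible(x)
}
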