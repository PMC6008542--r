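# Minimal EDF+C container support.
#
# EDF stores a 256-byte fixed-width ASCII header, 256 bytes of per-signal
# header fields (written field-major), then data records of little-endian
# 16-bit integers. EDF+ additionally requires an "EDF Annotations" signal
# whose first timestamp-annotation-list (TAL) per record carries the record
# onset. We write one annotation signal with timekeeping TALs only; artifact
# annotations live in sidecar CSV tables (bit-exact, diffable), not in TALs.

EDF_ANNOT_LABEL <- "EDF Annotations"
EDF_ANNOT_SPR <- 30L # 60 bytes of TAL space per record

# Fixed-width ASCII field, left-justified, space padded.
edf_field <- function(x, width) {
  s <- as.character(x)
  s <- iconv(s, to = "ASCII", sub = "?")
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

# Numeric in at most `width` ASCII chars.
edf_num <- function(v, width = 8) {
  for (d in 7:1) {
    s <- formatC(v, format = "g", digits = d)
    if (nchar(s) <= width) return(edf_field(s, width))
  }
  scc_abort("scclfp_value_error", "numeric field does not fit EDF header")
}

#' Write a recording to an EDF+ file
#'
#' Encodes the recording as EDF+C: one data record per second when the
#' sample count divides evenly, otherwise a single record spanning the whole
#' signal. Each channel is scaled to its own symmetric physical range so the
#' 16-bit quantization step is `max(abs(x)) / 32767` per channel.
#'
#' @param recording An [lfp_recording].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "lfp_recording"))
  x <- recording$samples
  if (!all(is.finite(x)))
    scc_abort("scclfp_value_error", "cannot write non-finite samples to EDF")
  fs <- recording$rate_hz
  n <- ncol(x)
  ns <- nrow(x)
  if (n < 1) scc_abort("scclfp_value_error", "recording has no samples")

  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    rec_dur <- 1
    spr <- as.integer(round(fs))
    n_rec <- as.integer(n / spr)
  } else {
    rec_dur <- n / fs
    spr <- n
    n_rec <- 1L
  }

  # per-channel symmetric physical range; slight headroom keeps the extreme
  # sample inside the digital range after rounding. Encoding uses the exact
  # physical values as they will be parsed back from the 8-char header
  # fields, and the standard EDF linear map over [dig_min, dig_max].
  pm <- apply(abs(x), 1, max)
  pm[pm == 0] <- 1
  # format the magnitude in 7 chars so "-<magnitude>" also fits its 8-char
  # header field and the two parse back to an exactly symmetric range
  pm <- vapply(signif(pm * 1.000001, 7),
               function(v) as.numeric(trimws(edf_num(v, 7))), 0)
  # digital range -32767..32767: symmetric with an exact zero code
  dig <- round(sweep(x, 1, pm / 32767, "/"))
  dig[dig > 32767] <- 32767
  dig[dig < -32767] <- -32767

  ns_tot <- ns + 1L # + annotation signal
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s) writeChar(s, con, eos = NULL)

  put(edf_field("0", 8))
  put(edf_field(recording$patient_id, 80))
  put(edf_field("Startdate 01-JAN-2000 X X X", 80))
  put(edf_field("01.01.00", 8))
  put(edf_field("00.00.00", 8))
  put(edf_field(256 * (ns_tot + 1), 8))
  put(edf_field("EDF+C", 44))
  put(edf_field(n_rec, 8))
  put(edf_num(rec_dur, 8))
  put(edf_field(ns_tot, 4))

  labels <- c(recording$channel_labels, EDF_ANNOT_LABEL)
  for (lab in labels) put(edf_field(lab, 16))
  for (i in seq_len(ns_tot)) put(edf_field("", 80)) # transducer
  for (i in seq_len(ns_tot)) put(edf_field(if (i <= ns) "uV" else "", 8))
  for (i in seq_len(ns_tot)) put(edf_num(if (i <= ns) -pm[i] else -1, 8))
  for (i in seq_len(ns_tot)) put(edf_num(if (i <= ns) pm[i] else 1, 8))
  for (i in seq_len(ns_tot)) put(edf_field(-32767, 8))
  for (i in seq_len(ns_tot)) put(edf_field(32767, 8))
  for (i in seq_len(ns_tot)) put(edf_field("", 80)) # prefiltering
  for (i in seq_len(ns_tot))
    put(edf_field(if (i <= ns) spr else EDF_ANNOT_SPR, 8))
  for (i in seq_len(ns_tot)) put(edf_field("", 32)) # reserved

  storage.mode(dig) <- "integer"
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    writeBin(as.vector(t(dig[, idx, drop = FALSE])), con,
             size = 2, endian = "little")
    tal <- sprintf("+%g\x14\x14", (r - 1) * rec_dur)
    ann <- raw(2 * EDF_ANNOT_SPR)
    ann[seq_len(nchar(tal))] <- charToRaw(tal)
    writeBin(ann, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into an [lfp_recording]
#'
#' Annotation signals are skipped. Channel labels recognizable as DBS
#' contacts are canonicalized to `L1..R4` (case-insensitive); when all data
#' channels are recognized the channels are reordered ventral-to-dorsal
#' `L1..L4, R1..R4`. If the container stores mixed sampling rates, the
#' slower signals are resampled to the fastest rate.
#'
#' @param path EDF file path.
#' @return An [lfp_recording] with samples in the file's physical units
#'   (microvolts for files written by [write_edf()]).
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    scc_abort("scclfp_format_error", sprintf("no such file: %s", path))
  fsize <- file.info(path)$size
  if (fsize < 256)
    scc_abort("scclfp_format_error", "file too short to hold an EDF header")
  con <- file(path, "rb")
  on.exit(close(con))
  grab <- function(width) readChar(con, width, useBytes = TRUE)
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) scc_abort("scclfp_format_error", "malformed numeric header field")
    v
  }

  version <- trimws(grab(8))
  if (version != "0")
    scc_abort("scclfp_format_error", "not an EDF file (bad version field)")
  patient <- trimws(grab(80))
  grab(80); grab(8); grab(8) # recording id, date, time
  num(grab(8)) # header bytes (recomputed below)
  grab(44)
  n_rec <- as.integer(num(grab(8)))
  rec_dur <- num(grab(8))
  ns_tot <- as.integer(num(grab(4)))
  if (ns_tot < 1)
    scc_abort("scclfp_empty_recording_error", "EDF file declares zero signals")

  fld <- function(width) vapply(seq_len(ns_tot), function(i) grab(width), "")
  labels <- trimws(fld(16))
  fld(80) # transducer
  fld(8)  # dimension
  phys_min <- vapply(fld(8), num, 0)
  phys_max <- vapply(fld(8), num, 0)
  dig_min <- vapply(fld(8), num, 0)
  dig_max <- vapply(fld(8), num, 0)
  fld(80) # prefiltering
  spr <- vapply(fld(8), num, 0)
  fld(32)

  data_sig <- which(labels != EDF_ANNOT_LABEL)
  if (length(data_sig) == 0)
    scc_abort("scclfp_empty_recording_error", "EDF file contains no data signals")

  rec_len <- sum(spr)
  expected <- 256 * (ns_tot + 1) + 2 * n_rec * rec_len
  if (fsize < expected)
    scc_abort("scclfp_format_error", "truncated EDF file (fewer bytes than header declares)")

  dat <- readBin(con, integer(), n = n_rec * rec_len, size = 2,
                 endian = "little", signed = TRUE)
  offsets <- c(0, cumsum(spr))

  signals <- lapply(data_sig, function(i) {
    pos <- as.vector(outer(offsets[i] + seq_len(spr[i]),
                           (seq_len(n_rec) - 1) * rec_len, "+"))
    d <- dat[pos]
    if (dig_max[i] == dig_min[i])
      scc_abort("scclfp_format_error", "degenerate digital range in header")
    (d - dig_min[i]) * (phys_max[i] - phys_min[i]) /
      (dig_max[i] - dig_min[i]) + phys_min[i]
  })

  rates <- spr[data_sig] / rec_dur
  rate <- max(rates)
  if (any(rates != rate)) {
    # mixed-rate container: bring every signal up to the fastest rate
    signals <- lapply(seq_along(signals), function(k) {
      if (rates[k] == rate) return(signals[[k]])
      fft_resample(signals[[k]], round(length(signals[[k]]) * rate / rates[k]))
    })
    len <- max(lengths(signals))
    signals <- lapply(signals, function(s) {
      length(s) <- len
      s[is.na(s)] <- 0
      s
    })
  }

  samples <- do.call(rbind, signals)
  labs <- labels[data_sig]
  canon <- canonical_contact(labs)
  labs <- ifelse(is.na(canon), labs, canon)
  if (!anyNA(canon) && !anyDuplicated(labs)) {
    ord <- order(match(labs, contact_labels()))
    samples <- samples[ord, , drop = FALSE]
    labs <- labs[ord]
  }
  lfp_recording(samples, rate, labs, patient_id = patient)
}
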