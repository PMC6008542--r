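# Seeded synthetic LFP generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: a 1/f^chi
# background (a shared common-mode component plus contact-specific
# components, so bipolar derivation cancels the common mode but not the
# local oscillations), band-limited oscillations whose post-stimulation
# amplitudes are multiplicatively scaled, amplifier-saturation segments
# during stimulation, and annotated high-amplitude artifact transients.
# Under the magnitude-based relative-change estimator the ground-truth band
# change is (multiplier - 1); under squared power it is (multiplier^2 - 1).

#' Synthetic stimulation-cycle specification
#'
#' Defaults describe one intraoperative cycle: 1 min pre, 3 min
#' stimulation, 1 min post at a native digitization rate of 1024 Hz, with
#' ~10 uV band oscillations over a 1/f background and occasional annotated
#' 150 uV transients.
#'
#' @param band_amplitudes_pre Named amplitudes (uV) of the five band
#'   oscillations in the pre epoch.
#' @param post_multipliers Named positive amplitude multipliers applied to
#'   the ipsilateral oscillations in the post epoch.
#' @param noise_exponent Spectral slope chi of the 1/f^chi backgrounds,
#'   in \[0, 2\].
#' @param noise_scale SD (uV) of each contact-specific background.
#' @param common_scale SD (uV) of the shared common-mode background
#'   (cancelled by bipolar derivation).
#' @param artifact_rate Expected artifact transients per minute per channel
#'   within the analyzed pre/post windows.
#' @param artifact_amp_uV,artifact_dur_s Transient amplitude and duration.
#' @param sat_amp_uV Amplifier-saturation amplitude during stimulation.
#' @param rate_hz Native sampling rate.
#' @param stim_contact,role,patient_id Cycle metadata.
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return List of class `cycle_spec`.
#' @export
cycle_spec <- function(band_amplitudes_pre = c(delta = 10, theta = 10,
                                               alpha = 10, beta = 10,
                                               gamma = 10),
                       post_multipliers = c(delta = 1, theta = 1, alpha = 1,
                                            beta = 1, gamma = 1),
                       noise_exponent = 1, noise_scale = 1,
                       common_scale = 20,
                       artifact_rate = 0.3, artifact_amp_uV = 150,
                       artifact_dur_s = 0.5, sat_amp_uV = 500,
                       rate_hz = 1024,
                       stim_contact = "L2", role = "effective",
                       patient_id = "sim", seed = 1) {
  bands <- names(scc_band_edges())
  stopifnot(all(bands %in% names(band_amplitudes_pre)),
            all(bands %in% names(post_multipliers)))
  if (any(post_multipliers <= 0))
    scc_abort("scclfp_value_error", "post multipliers must be positive")
  if (noise_exponent < 0 || noise_exponent > 2)
    scc_abort("scclfp_value_error", "noise exponent must lie in [0, 2]")
  structure(list(band_amplitudes_pre = band_amplitudes_pre[bands],
                 post_multipliers = post_multipliers[bands],
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 common_scale = common_scale, artifact_rate = artifact_rate,
                 artifact_amp_uV = artifact_amp_uV,
                 artifact_dur_s = artifact_dur_s, sat_amp_uV = sat_amp_uV,
                 rate_hz = rate_hz, stim_contact = stim_contact,
                 role = role, patient_id = patient_id, seed = seed),
            class = "cycle_spec")
}

#' Gaussian 1/f^chi background noise
#'
#' Spectral shaping of white Gaussian noise: Fourier amplitudes are scaled
#' by `f^(-chi/2)` (flattened below 0.5 Hz so slow drift does not dominate
#' the variance), then the signal is standardized to SD `scale`.
#' Stationary; reproducible given `seed`.
#'
#' @param duration_s,rate_hz Signal duration and rate.
#' @param exponent Spectral slope chi in \[0, 2\].
#' @param scale Output standard deviation (uV).
#' @param seed Optional integer seed.
#' @return Numeric vector of `round(duration_s * rate_hz)` samples.
#' @export
generate_background <- function(duration_s, rate_hz, exponent = 1,
                                scale = 1, seed = NULL) {
  if (exponent < 0 || exponent > 2)
    scc_abort("scclfp_value_error", "noise exponent must lie in [0, 2]")
  n <- round(duration_s * rate_hz)
  with_seed(seed, {
    w <- stats::rnorm(n)
    W <- stats::fft(w)
    f <- (seq_len(n) - 1) / n * rate_hz
    f <- pmin(f, rate_hz - f) # two-sided frequency magnitude
    shape <- pmax(f, 0.5)^(-exponent / 2)
    shape[1] <- 0
    x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
    if (scale == 0 || stats::sd(x) == 0) numeric(n)
    else x / stats::sd(x) * scale
  })
}

#' Narrowband oscillation confined to a frequency band
#'
#' Frequency-domain synthesis: complex Gaussian spectrum masked to the
#' band's interior with raised-cosine edges, inverse transformed, and
#' scaled so the RMS equals `amplitude / sqrt(2)` (the RMS of a sinusoid of
#' that amplitude). At least ~99% of the power lies inside the band.
#'
#' @param band One of `"delta","theta","alpha","beta","gamma"`.
#' @param amplitude Oscillation amplitude (uV); 0 gives a zero signal.
#' @param duration_s,rate_hz Duration and rate.
#' @param seed Optional integer seed.
#' @return Numeric vector of samples.
#' @export
generate_band_oscillation <- function(band, amplitude, duration_s, rate_hz,
                                      seed = NULL) {
  edges <- scc_band_edges()[[match.arg(band, names(scc_band_edges()))]]
  n <- round(duration_s * rate_hz)
  if (amplitude == 0) return(numeric(n))
  lo <- edges[1]; hi <- edges[2]
  taper <- min(0.5, (hi - lo) / 8)
  with_seed(seed, {
    f <- (seq_len(n) - 1) / n * rate_hz
    half <- f <= rate_hz / 2
    ramp_up <- pmin(1, pmax(0, (f - lo) / taper))
    ramp_dn <- pmin(1, pmax(0, (hi - f) / taper))
    mask <- ifelse(half & f >= lo & f <= hi,
                   sin(ramp_up * pi / 2) * sin(ramp_dn * pi / 2), 0)
    spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * mask
    # hermitian symmetry for a real signal
    idx <- 2:ceiling(n / 2)
    spec[n + 2 - idx] <- Conj(spec[idx])
    spec[1] <- 0
    if (n %% 2 == 0) spec[n / 2 + 1] <- Re(spec[n / 2 + 1])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x / sqrt(mean(x^2)) * amplitude / sqrt(2)
  })
}

# --- session engine -------------------------------------------------------

# Build the 8-channel referential signal matrix for a set of cycles.
# `cycles` is a data.frame with stim_on_s, stim_off_s, hemisphere and a
# list-column `multipliers` (named per band). Only the analyzed pre/post
# minutes carry synthesized LFP (fresh stationary realizations per window,
# with the post multipliers applied as generated oscillation amplitudes on
# the ipsilateral contacts); the stimulation interval itself is overwritten
# with amplifier saturation, exactly as the real recordings are unusable
# there. Returns the samples matrix.
synth_session_signals <- function(spec, cycles, duration_s, seed) {
  rate <- spec$rate_hz
  n <- round(duration_s * rate)
  bands <- names(scc_band_edges())
  contacts <- contact_labels()
  samples <- matrix(0, nrow = length(contacts), ncol = n,
                    dimnames = list(contacts, NULL))
  win_idx <- function(a, b) {
    i <- seq.int(max(1, floor(a * rate) + 1), min(n, ceiling(b * rate)))
    i[(i - 1) / rate >= a & (i - 1) / rate < b]
  }
  for (k in seq_len(nrow(cycles))) {
    for (w in c("pre", "post")) {
      a <- if (w == "pre") cycles$stim_on_s[k] - 60 else cycles$stim_off_s[k]
      idx <- win_idx(a, a + 60)
      dur <- length(idx) / rate
      common <- generate_background(dur, rate, spec$noise_exponent,
                                    spec$common_scale,
                                    mix_seed(seed, "common", k, w))
      for (ct in contacts) {
        x <- common + generate_background(dur, rate, spec$noise_exponent,
                                          spec$noise_scale,
                                          mix_seed(seed, "bg", k, w, ct))
        ipsi <- cycles$hemisphere[k] == substr(ct, 1, 1)
        for (b in bands) {
          amp <- spec$band_amplitudes_pre[[b]]
          if (w == "post" && ipsi) amp <- amp * cycles$multipliers[[k]][[b]]
          if (amp == 0) next
          x <- x + generate_band_oscillation(b, amp, dur, rate,
                                             mix_seed(seed, "osc", k, w, ct, b))
        }
        samples[ct, idx] <- x
      }
    }
    # amplifier saturation during stimulation: a clipped high-frequency
    # square wave, slightly different gain per channel so the bipolar
    # residual is nonzero (as for real hardware)
    idx <- win_idx(cycles$stim_on_s[k], cycles$stim_off_s[k])
    tk <- (idx - 1) / rate
    sat <- spec$sat_amp_uV * sign(sin(2 * pi * 130 * tk) + 1e-12)
    for (ci in seq_along(contacts)) {
      gain <- with_seed(mix_seed(seed, "sat", contacts[ci], k),
                        stats::runif(1, 0.95, 1.05))
      samples[ci, idx] <- gain * sat
    }
  }
  samples
}

# Inject annotated artifact transients into the pre/post windows of each
# cycle. Modifies `samples` and returns list(samples, annotations). The
# emitted annotations pad the pulse by 0.25 s on each side so that filter
# ringing around the pulse edges is also pruned downstream.
synth_inject_artifacts <- function(samples, spec, cycles, seed) {
  rate <- spec$rate_hz
  n <- ncol(samples)
  tv <- (seq_len(n) - 1) / rate
  rows <- list()
  for (k in seq_len(nrow(cycles))) {
    windows <- rbind(c(cycles$stim_on_s[k] - 60, cycles$stim_on_s[k]),
                     c(cycles$stim_off_s[k], cycles$stim_off_s[k] + 60))
    for (w in 1:2) {
      for (ct in rownames(samples)) {
        sd_art <- mix_seed(seed, "art", k, w, ct)
        count <- with_seed(sd_art, stats::rpois(1, spec$artifact_rate))
        if (count == 0) next
        starts <- with_seed(mix_seed(sd_art, 1),
                            stats::runif(count, windows[w, 1] + 3,
                                         windows[w, 2] - spec$artifact_dur_s - 3))
        signs <- with_seed(mix_seed(sd_art, 2),
                           sample(c(-1, 1), count, replace = TRUE))
        for (j in seq_len(count)) {
          idx <- which(tv >= starts[j] & tv < starts[j] + spec$artifact_dur_s)
          samples[ct, idx] <- samples[ct, idx] +
            signs[j] * spec$artifact_amp_uV
          rows[[length(rows) + 1]] <- data.frame(
            channel = ct, start_s = starts[j] - 0.25,
            end_s = starts[j] + spec$artifact_dur_s + 0.25)
        }
      }
    }
    # guard annotations around the stimulation transitions, where the
    # saturation edges ring through the zero-phase bandpass in both
    # directions
    rows[[length(rows) + 1]] <- data.frame(
      channel = "all", start_s = cycles$stim_on_s[k] - 2,
      end_s = cycles$stim_on_s[k] + 2)
    rows[[length(rows) + 1]] <- data.frame(
      channel = "all", start_s = cycles$stim_off_s[k] - 2,
      end_s = cycles$stim_off_s[k] + 2)
  }
  ann <- if (length(rows)) do.call(rbind, rows)
         else data.frame(channel = character(), start_s = numeric(),
                         end_s = numeric())
  list(samples = samples, annotations = ann)
}

#' Synthesize one stimulation cycle with known ground truth
#'
#' Generates a 300 s, 8-channel referential recording (1 min pre, 3 min
#' saturated stimulation, 1 min post; stimulation onset at 60 s), the cycle
#' metadata row, the artifact annotation table, and the ground-truth band
#' changes implied by the post multipliers: `multiplier - 1` under CWT
#' moduli and `multiplier^2 - 1` under squared power.
#'
#' @param spec A [cycle_spec()].
#' @return List with `recording` ([lfp_recording]), `cycle` (data.frame
#'   row), `artifacts` (annotation data.frame) and `truth` (list with
#'   `amplitude` and `power` named band vectors).
#' @export
synthesize_cycle <- function(spec) {
  stopifnot(inherits(spec, "cycle_spec"))
  hemi <- substr(canonical_contact(spec$stim_contact), 1, 1)
  cycles <- data.frame(stim_on_s = 60, stim_off_s = 240, hemisphere = hemi)
  cycles$multipliers <- list(as.list(spec$post_multipliers))
  samples <- synth_session_signals(spec, cycles, 300, spec$seed)
  inj <- synth_inject_artifacts(samples, spec, cycles, spec$seed)
  rec <- lfp_recording(inj$samples, spec$rate_hz, contact_labels(),
                       patient_id = spec$patient_id)
  cycle <- data.frame(patient_id = spec$patient_id,
                      stim_contact = canonical_contact(spec$stim_contact),
                      hemisphere = hemi, role = spec$role,
                      stim_on_s = 60, stim_off_s = 240)
  truth <- list(amplitude = spec$post_multipliers - 1,
                power = spec$post_multipliers^2 - 1)
  list(recording = rec, cycle = cycle, artifacts = inj$annotations,
       truth = truth)
}

#' Synthetic cohort specification
#'
#' Defaults reproduce the study design: 14 patients, 11 six-month
#' responders, 4 analyzed cycles per patient (effective and ineffective
#' contacts in each hemisphere), 8 channels, giving 14 x 8 x 4 x 2 = 896
#' pre/post epochs. Responders carry the asymmetric ipsilateral effect
#' profile (left effective: theta/alpha/beta/gamma suppression; right
#' effective: beta/gamma only; ineffective contacts similar but without the
#' left theta effect); non-responders have null effects. One patient has an
#' edge effective contact (no left differential), one non-responder has a
#' fully artifacted epoch, and one patient lacks the weekly HDRS17 series.
#'
#' @param n_patients,n_responders Cohort sizes.
#' @param left_effective,right_effective,left_ineffective,right_ineffective
#'   Named amplitude multipliers per band for the post epoch of each cycle
#'   type (responders only).
#' @param edge_contact_patient Index of the patient whose left effective
#'   contact is L4 (set 0 to disable).
#' @param fully_artifacted_patient Index of the patient whose left
#'   effective pre epoch is entirely annotated as artifact (0 disables).
#' @param missing_weekly_patient Index of the patient without a weekly
#'   HDRS17 series (0 disables).
#' @param cycle A [cycle_spec()] providing the signal-level parameters.
#' @param master_seed Master integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 14, n_responders = 11,
                        left_effective = c(delta = 1, theta = 0.5,
                                           alpha = 0.5, beta = 0.7,
                                           gamma = 0.7),
                        right_effective = c(delta = 1, theta = 1, alpha = 1,
                                            beta = 0.7, gamma = 0.7),
                        left_ineffective = c(delta = 1, theta = 1,
                                             alpha = 0.7, beta = 0.6,
                                             gamma = 0.7),
                        right_ineffective = c(delta = 1, theta = 1,
                                              alpha = 1, beta = 0.75,
                                              gamma = 0.8),
                        edge_contact_patient = 5,
                        fully_artifacted_patient = 12,
                        missing_weekly_patient = 14,
                        cycle = cycle_spec(),
                        master_seed = 1) {
  stopifnot(n_responders <= n_patients, n_patients >= 1)
  structure(list(n_patients = n_patients, n_responders = n_responders,
                 profiles = list(L_effective = left_effective,
                                 R_effective = right_effective,
                                 L_ineffective = left_ineffective,
                                 R_ineffective = right_ineffective),
                 edge_contact_patient = edge_contact_patient,
                 fully_artifacted_patient = fully_artifacted_patient,
                 missing_weekly_patient = missing_weekly_patient,
                 cycle = cycle, master_seed = master_seed),
            class = "cohort_spec")
}

# Clinical scores consistent with the configured responder split, with
# weekly series whose first stable 3-week run starts at a known week.
synth_clinical <- function(spec) {
  n <- spec$n_patients
  rows <- lapply(seq_len(n), function(p) {
    sd_p <- mix_seed(spec$master_seed, "clin", p)
    with_seed(sd_p, {
      baseline <- sample(seq(20, 29.25, by = 0.25), 1)
      responder <- p <= spec$n_responders
      month6 <- if (responder) round(baseline * stats::runif(1, 0.2, 0.45))
                else round(baseline * stats::runif(1, 0.55, 0.8))
      weekly <- if (p == spec$missing_weekly_patient) {
        ""
      } else if (responder) {
        w0 <- sample(3:20, 1)
        pre <- round(baseline * stats::runif(w0 - 1, 0.55, 0.95))
        post <- round(baseline * stats::runif(26 - w0 + 1, 0.2, 0.45))
        paste(c(pre, post), collapse = ";")
      } else {
        paste(round(baseline * stats::runif(26, 0.55, 0.95)), collapse = ";")
      }
      data.frame(patient_id = sprintf("P%02d", p),
                 baseline_hdrs17 = baseline, month6_hdrs17 = month6,
                 weekly_hdrs17 = weekly)
    })
  })
  do.call(rbind, rows)
}

#' Synthesize a full cohort dataset directory
#'
#' Writes one EDF+ file per patient (four 300 s cycles back to back,
#' 1200 s x 8 channels) plus `cycles.csv`, `artifacts.csv`, `clinical.csv`
#' and `truth.json` (the ground-truth band changes per cycle under both
#' magnitude and squared-power conventions). Byte-reproducible from
#' `master_seed`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synthesize_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bands <- names(scc_band_edges())
  cyc <- spec$cycle
  all_cycles <- list(); all_art <- list(); truth <- list()

  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", p)
    sd_p <- mix_seed(spec$master_seed, "patient", p)
    responder <- p <= spec$n_responders
    picks <- with_seed(mix_seed(sd_p, "contacts"), {
      list(L = sample(c("L2", "L3"), 1), R = sample(c("R2", "R3"), 1))
    })
    eff <- list(L = picks$L, R = picks$R)
    if (p == spec$edge_contact_patient) eff$L <- "L4"
    ineff <- list(L = if (eff$L == "L2") "L3" else "L3",
                  R = if (eff$R == "R2") "R3" else "R2")
    if (eff$L == "L3") ineff$L <- "L2"

    defs <- list(list(hemi = "L", role = "effective", contact = eff$L),
                 list(hemi = "R", role = "effective", contact = eff$R),
                 list(hemi = "L", role = "ineffective", contact = ineff$L),
                 list(hemi = "R", role = "ineffective", contact = ineff$R))
    ord <- with_seed(mix_seed(sd_p, "order"), sample(seq_along(defs)))
    defs <- defs[ord]

    cycles <- do.call(rbind, lapply(seq_along(defs), function(k) {
      data.frame(patient_id = pid, stim_contact = defs[[k]]$contact,
                 hemisphere = defs[[k]]$hemi, role = defs[[k]]$role,
                 stim_on_s = (k - 1) * 300 + 60,
                 stim_off_s = (k - 1) * 300 + 240)
    }))
    cycles$multipliers <- lapply(seq_along(defs), function(k) {
      if (!responder) return(as.list(stats::setNames(rep(1, 5), bands)))
      as.list(spec$profiles[[paste(defs[[k]]$hemi, defs[[k]]$role,
                                   sep = "_")]])
    })

    samples <- synth_session_signals(cyc, cycles, 1200, sd_p)
    inj <- synth_inject_artifacts(samples, cyc, cycles, sd_p)
    art <- inj$annotations
    if (nrow(art)) art <- cbind(patient_id = pid, art)

    if (p == spec$fully_artifacted_patient) {
      k <- which(cycles$hemisphere == "L" & cycles$role == "effective")[1]
      art <- rbind(art, data.frame(patient_id = pid, channel = "all",
                                   start_s = cycles$stim_on_s[k] - 60,
                                   end_s = cycles$stim_on_s[k]))
    }

    rec <- lfp_recording(inj$samples, cyc$rate_hz, contact_labels(),
                         patient_id = pid)
    write_edf(rec, file.path(dir, sprintf("patient_%02d.edf", p)))

    all_cycles[[p]] <- cycles[, setdiff(names(cycles), "multipliers")]
    all_art[[p]] <- art
    truth[[pid]] <- lapply(seq_along(defs), function(k) {
      m <- unlist(cycles$multipliers[[k]])
      list(stim_contact = defs[[k]]$contact, hemisphere = defs[[k]]$hemi,
           role = defs[[k]]$role,
           amplitude = as.list(m - 1), power = as.list(m^2 - 1))
    })
    rm(samples, inj, rec)
  }

  utils::write.csv(do.call(rbind, all_cycles),
                   file.path(dir, "cycles.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, all_art),
                   file.path(dir, "artifacts.csv"), row.names = FALSE)
  utils::write.csv(synth_clinical(spec),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
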