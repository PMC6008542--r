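# End-to-end orchestration: dataset directory -> per-cycle band changes ->
# group test table + clinical summary + run report, with every epoch
# accounted for as analyzed, skipped-with-reason, or errored.

#' Pipeline run configuration
#'
#' Bundles every analysis constant. All randomness flows from `seed`
#' through named substreams, so a config plus a dataset determines the
#' outputs byte for byte.
#'
#' @param dataset_dir Dataset directory (EDF files plus `cycles.csv`,
#'   `artifacts.csv`, `clinical.csv`).
#' @param out_dir Output directory; results land in a
#'   `run-<confighash>` subdirectory.
#' @param low_hz,high_hz Bandpass edges (1, 50).
#' @param target_hz Analysis rate (128).
#' @param n_boot,ci_level Bootstrap replicates and CI level.
#' @param seed Master seed.
#' @param n_cycles Morlet cycles per frequency.
#' @param use_power Bootstrap squared CWT magnitudes instead of moduli.
#' @param splice_guard_s Seconds dropped around each pruned artifact splice
#'   (default 0 = plain discard-and-concatenate).
#' @param alpha Family-wise significance level (Bonferroni over 5 bands).
#' @param method One-sample test method for the group table.
#' @param responders_only Restrict group statistics to 6-month responders.
#' @return List of class `run_config`.
#' @export
run_config <- function(dataset_dir, out_dir = file.path(dataset_dir, "out"),
                       low_hz = 1, high_hz = 50, target_hz = 128,
                       n_boot = 1000, ci_level = 0.95, seed = 1,
                       n_cycles = 6, use_power = FALSE, splice_guard_s = 0,
                       alpha = 0.05,
                       method = c("signed_rank", "rank_sum_vs_zero"),
                       responders_only = TRUE) {
  structure(list(dataset_dir = dataset_dir, out_dir = out_dir,
                 low_hz = low_hz, high_hz = high_hz, target_hz = target_hz,
                 n_boot = n_boot, ci_level = ci_level, seed = seed,
                 n_cycles = n_cycles, use_power = use_power,
                 splice_guard_s = splice_guard_s, alpha = alpha,
                 method = match.arg(method),
                 responders_only = responders_only),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file (e.g. from CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    scc_abort("scclfp_config_error",
              sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(run_config, vals)
}

dataset_files <- function(dir) {
  list(edf = sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE)),
       cycles = file.path(dir, "cycles.csv"),
       artifacts = file.path(dir, "artifacts.csv"),
       clinical = file.path(dir, "clinical.csv"))
}

#' Validate a run configuration and its dataset
#'
#' @param config A `run_config`.
#' @return Character vector of findings (empty when everything checks
#'   out), with attribute `fatal` flagging findings that preclude a run.
#' @export
validate_config <- function(config) {
  findings <- character()
  fatal <- logical()
  note <- function(msg, is_fatal = FALSE) {
    findings <<- c(findings, msg)
    fatal <<- c(fatal, is_fatal)
  }
  if (config$n_boot < 100) note("n_boot below minimum of 100", TRUE)
  if (config$ci_level <= 0 || config$ci_level >= 1)
    note("ci_level must lie in (0, 1)", TRUE)
  if (config$target_hz <= 2 * config$high_hz)
    note("analysis rate below twice the passband edge", TRUE)
  fs <- dataset_files(config$dataset_dir)
  if (!dir.exists(config$dataset_dir)) {
    note("dataset directory does not exist", TRUE)
  } else {
    if (length(fs$edf) == 0) note("dataset contains no EDF files", TRUE)
    for (f in c("cycles", "artifacts", "clinical"))
      if (!file.exists(fs[[f]]))
        note(sprintf("dataset missing %s.csv", f), f == "cycles")
  }
  attr(findings, "fatal") <- fatal
  findings
}

#' Inventory a dataset directory
#'
#' Counts patients, channels, cycles, and nominal pre/post epochs
#' (channels x cycles x 2, referential channels counted per patient).
#'
#' @param dataset_dir Dataset directory.
#' @return List with `n_patients`, `n_cycles`, `n_epochs` and a per-patient
#'   table.
#' @export
describe_dataset <- function(dataset_dir) {
  fs <- dataset_files(dataset_dir)
  if (!file.exists(fs$cycles))
    scc_abort("scclfp_schema_error", "dataset missing cycles.csv")
  cycles <- read_cycle_table(fs$cycles)
  per <- lapply(fs$edf, function(f) {
    rec <- read_edf(f)
    nc <- sum(rec$patient_id == cycles$patient_id)
    data.frame(patient_id = rec$patient_id, file = basename(f),
               n_channels = nrow(rec$samples), rate_hz = rec$rate_hz,
               n_cycles = nc, n_epochs = nrow(rec$samples) * nc * 2)
  })
  per <- do.call(rbind, per)
  list(n_patients = nrow(per), n_cycles = sum(per$n_cycles),
       n_epochs = sum(per$n_epochs), patients = per)
}

#' Run the full analysis pipeline
#'
#' For every stimulation cycle: reads the patient's EDF recording, applies
#' the zero-phase 1-50 Hz bandpass at the native rate, decimates to
#' 128 Hz, derives the ipsilateral bipolar differential around the
#' stimulated contact, prunes annotated artifacts (discard, not blank),
#' extracts the pre/post minute epochs and estimates the five band-limited
#' relative power changes via the bootstrap CWT analysis. Cycles that
#' cannot be analyzed (edge contacts, fully pruned epochs) are recorded
#' and skipped; the run continues. Group statistics, the clinical summary
#' and a provenance report are then written under
#' `out_dir/run-<confighash>/`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `band_changes`, `test_table`,
#'   `clinical_summary`, `report`, `qc` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (any(attr(findings, "fatal")))
    scc_abort("scclfp_config_error",
              paste("fatal config findings:",
                    paste(findings[attr(findings, "fatal")], collapse = "; ")))
  fs <- dataset_files(config$dataset_dir)
  cycles <- read_cycle_table(fs$cycles)
  artifacts <- if (file.exists(fs$artifacts)) read_artifact_table(fs$artifacts)
               else data.frame(patient_id = character(),
                               channel = character(),
                               start_s = numeric(), end_s = numeric())
  clinical <- read_clinical_table(fs$clinical)
  outcomes <- patient_outcomes(clinical)

  band_rows <- list(); qc_rows <- list(); log_rows <- list()
  bands <- names(scc_band_edges())
  cycle_counter <- 0

  for (edf_path in fs$edf) {
    rec <- read_edf(edf_path)
    pid <- rec$patient_id
    pcycles <- cycles[cycles$patient_id == pid, , drop = FALSE]
    if (nrow(pcycles) == 0) next
    # filter -> decimate each referential channel once per patient
    dec <- t(apply(rec$samples, 1, function(x)
      decimate_to_rate(bandpass_zero_phase(x, rec$rate_hz, config$low_hz,
                                           config$high_hz),
                       rec$rate_hz, config$target_hz)))
    rec128 <- lfp_recording(dec, config$target_hz, rec$channel_labels,
                            patient_id = pid)
    rm(rec)

    for (k in seq_len(nrow(pcycles))) {
      cycle_counter <- cycle_counter + 1
      cyc <- pcycles[k, ]
      status <- tryCatch({
        diff_sig <- derive_differential(rec128, cyc$stim_contact)
        diff_sig <- mask_differential(diff_sig, artifacts, patient_id = pid,
                                      guard_s = config$splice_guard_s)
        pair <- extract_epoch_pair(diff_sig, cyc)
        sc <- spectral_config(
          n_boot = config$n_boot, ci_level = config$ci_level,
          seed = mix_seed(config$seed, "boot", pid, cyc$stim_contact),
          n_cycles = config$n_cycles, use_power = config$use_power)
        bc <- analyze_cycle(pair, sc)
        band_rows[[length(band_rows) + 1]] <- data.frame(
          patient_id = pid, hemisphere = cyc$hemisphere, role = cyc$role,
          stim_contact = cyc$stim_contact, band = bands,
          value = as.numeric(bc),
          ci_level = config$ci_level, n_boot = config$n_boot,
          seed = sc$seed)
        qc_rows[[length(qc_rows) + 1]] <- data.frame(
          patient_id = pid, stim_contact = cyc$stim_contact,
          role = cyc$role,
          lost_fraction_pre = pair$lost_fraction_pre,
          lost_fraction_post = pair$lost_fraction_post,
          n_pre = length(pair$pre), n_post = length(pair$post),
          n_segments_pre = pair$n_segments_pre,
          n_segments_post = pair$n_segments_post,
          n_nominal = pair$n_nominal)
        list(state = "analyzed", reason = "")
      },
      scclfp_no_differential_error = function(e)
        list(state = "skipped_no_differential", reason = conditionMessage(e)),
      scclfp_empty_epoch_error = function(e)
        list(state = "skipped_empty_epoch", reason = conditionMessage(e)),
      scclfp_error = function(e)
        list(state = "errored", reason = conditionMessage(e)))
      log_rows[[length(log_rows) + 1]] <- data.frame(
        patient_id = pid, stim_contact = cyc$stim_contact, role = cyc$role,
        state = status$state, reason = status$reason)
    }
    rm(rec128, dec)
  }

  band_changes <- if (length(band_rows)) do.call(rbind, band_rows)
                  else data.frame()
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else data.frame()
  cycle_log <- if (length(log_rows)) do.call(rbind, log_rows)
               else data.frame()

  test_table <- if (nrow(band_changes))
    build_test_table(band_changes, outcomes, alpha = config$alpha,
                     method = config$method,
                     responders_only = config$responders_only)
  else NULL
  summary <- cohort_summary(outcomes)

  if (nrow(band_changes) == 0)
    scc_warn("scclfp_empty_run_warning",
             "no cycle could be analyzed; band table is empty")

  states <- if (nrow(cycle_log)) table(cycle_log$state) else table(character())
  report <- list(
    config = unclass(config),
    inventory = list(n_patients = length(fs$edf),
                     n_cycles = nrow(cycles),
                     n_cycles_seen = cycle_counter),
    accounting = as.list(states),
    n_missing_differential =
      sum(cycle_log$state == "skipped_no_differential"),
    qc_total_lost_fraction = if (nrow(qc))
      sum(qc$lost_fraction_pre * qc$n_nominal / 2 +
          qc$lost_fraction_post * qc$n_nominal / 2) / sum(qc$n_nominal)
      else NA,
    cycle_log = cycle_log)

  run_dir <- file.path(config$out_dir,
                       paste0("run-", tiny_digest(unclass(config))))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(band_changes))
    utils::write.table(band_changes, file.path(run_dir, "band_changes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(test_table))
    utils::write.table(as.data.frame(test_table),
                       file.path(run_dir, "test_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (nrow(qc))
    utils::write.table(qc, file.path(run_dir, "qc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, file.path(run_dir, "clinical_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  invisible(list(band_changes = band_changes, test_table = test_table,
                 clinical_summary = summary, report = report, qc = qc,
                 out_dir = run_dir))
}
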