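#' Read a beat-series CSV
#'
#' Reads one subject's beat-to-beat stream from a long-format CSV with
#' header `time_s,sbp_mmhg,hr_bpm`. Per-subject metadata (identifier,
#' baseline SBP, delivery time) travels outside the stream — pass it here
#' or keep it in a run manifest (see [write_run()]).
#'
#' @param path CSV file path.
#' @param subject_id Subject label.
#' @param baseline_sbp Baseline SBP, mmHg.
#' @param delivery_time_s Fetal delivery time, seconds; default last beat.
#' @return A [beat_series()].
#' @export
read_beat_series <- function(path, subject_id, baseline_sbp,
                             delivery_time_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "sbp_mmhg", "hr_bpm")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty beat-series file: ", path)
  for (cl in needed) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column ", cl, " at row ", bad, " of ", path)
    }
  }
  dup <- which(diff(df$time_s) <= 0)
  if (length(dup) > 0L)  # +2: header line plus 1-based offending data row
    stop("non-increasing time_s at row ", dup[1] + 2L, " of ", path)
  beat_series(subject_id, baseline_sbp, df$time_s, df$sbp_mmhg, df$hr_bpm,
              delivery_time_s = delivery_time_s)
}

#' Write a beat-series CSV
#'
#' @param series A [beat_series()].
#' @param path Output CSV path (header `time_s,sbp_mmhg,hr_bpm`).
#' @return `path`, invisibly.
#' @export
write_beat_series <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  df <- data.frame(time_s = series$samples$time_s,
                   sbp_mmhg = series$samples$sbp,
                   hr_bpm = series$samples$hr)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a dose-event log CSV
#'
#' Header `start_s,drug,amount,units,duration_s,mode,band,slope_mmhg_per_s`.
#'
#' @param events Dose-event data.frame from [controller_step()] /
#'   [simulate_closed_loop()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the events data.frame (reader).
#' @export
write_dose_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_events
#' @export
read_dose_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("start_s", "drug", "amount", "units", "duration_s", "mode",
              "band", "slope_mmhg_per_s")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Round-trip a controller configuration through YAML
#'
#' @param config A [controller_config()].
#' @param path YAML path.
#' @return `path` invisibly (writer); a [controller_config()] (reader).
#' @export
write_controller_config <- function(config, path) {
  stopifnot(inherits(config, "controller_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_controller_config
#' @export
read_controller_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(controller_config, raw)
}

#' Write a metrics report as JSON
#'
#' Emits a diffable JSON report (stable key order, units in key names)
#' with the per-subject and pooled performance-error statistics and
#' outcome summaries.
#'
#' @param per_patient data.frame of [per_patient_metrics()] rows.
#' @param summaries data.frame of [outcome_summary()] rows (optional).
#' @param path Output JSON path.
#' @param config Optional configuration snapshot to embed.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(per_patient, summaries = NULL, path,
                                 config = NULL) {
  report <- list(
    tool = "divasim",
    version = as.character(utils::packageVersion("divasim")),
    n_subjects = nrow(per_patient),
    per_patient = lapply(seq_len(nrow(per_patient)), function(i) {
      r <- per_patient[i, ]
      list(subject_id = r$subject_id, n_obs = r$n_obs,
           mdape_pct = r$mdape, mdpe_pct = r$mdpe, wobble_pct = r$wobble,
           divergence_pct_per_min = r$divergence)
    }),
    pooled = if (nrow(per_patient) > 0L) {
      p <- pool_metrics(per_patient)
      list(mdape_pct = p$mdape, mdpe_pct = p$mdpe, wobble_pct = p$wobble,
           divergence_pct_per_min = p$divergence,
           total_obs = p$total_obs, n_subjects = p$n_subjects)
    } else NULL,
    outcomes = if (!is.null(summaries)) {
      bp <- band_proportion(summaries)
      list(n_hypotension = sum(summaries$hypotension),
           n_hypertension = sum(summaries$hypertension),
           n_bradycardia = sum(summaries$bradycardia),
           prop_below_80_pct = 100 * bp$prop_below_80,
           prop_within_80_120_pct = 100 * bp$prop_within_80_120,
           total_phenylephrine_ug = sum(summaries$total_phenylephrine_ug),
           total_ephedrine_mg = sum(summaries$total_ephedrine_mg))
    } else NULL,
    config = config
  )
  report <- report[!vapply(report, is.null, logical(1))]
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a simulation run to disk
#'
#' Writes one beat-series CSV and one dose-event CSV per subject plus a
#' manifest CSV holding the per-subject metadata (subject id, baseline SBP,
#' delivery time, seed, file names, checksums) and a JSON snapshot of the
#' controller configuration — enough to re-run or re-analyze the run.
#'
#' @param runs List of results from [simulate_closed_loop()].
#' @param dir Output directory (created if needed).
#' @param config The [controller_config()] used.
#' @param master_seed Seed recorded in the manifest.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_run <- function(runs, dir, config, master_seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    beats <- file.path(dir, sprintf("subject_%03d_beats.csv", i))
    events <- file.path(dir, sprintf("subject_%03d_events.csv", i))
    write_beat_series(r$series, beats)
    write_dose_events(r$events, events)
    data.frame(subject_id = r$series$subject_id,
               baseline_sbp_mmhg = r$series$baseline_sbp,
               delivery_time_s = r$series$delivery_time_s,
               beats_file = basename(beats),
               events_file = basename(events),
               beats_md5 = unname(tools::md5sum(beats)),
               events_md5 = unname(tools::md5sum(events)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(cbind(manifest, master_seed = master_seed),
                   manifest_path, row.names = FALSE)
  write_controller_config(config, file.path(dir, "controller_config.yaml"))
  invisible(manifest_path)
}

#' Read a simulation run from disk
#'
#' @param dir Directory written by [write_run()].
#' @return list with `series` (list of [beat_series()]), `events` (list of
#'   event logs), `config` and the `manifest` data.frame.
#' @export
read_run <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  series <- lapply(seq_len(nrow(manifest)), function(i) {
    read_beat_series(file.path(dir, manifest$beats_file[i]),
                     subject_id = manifest$subject_id[i],
                     baseline_sbp = manifest$baseline_sbp_mmhg[i],
                     delivery_time_s = manifest$delivery_time_s[i])
  })
  events <- lapply(manifest$events_file,
                   function(f) read_dose_events(file.path(dir, f)))
  cfg_path <- file.path(dir, "controller_config.yaml")
  config <- if (file.exists(cfg_path)) read_controller_config(cfg_path)
  list(series = series, events = events, config = config,
       manifest = manifest)
}
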