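#' Write a study to disk in the pipeline's exchange layout
#'
#' Layout: one directory per participant with per-condition
#' subdirectories holding `eeg.tsv` + `eeg.json` (matrix + sidecar),
#' `events.tsv`, `presses.tsv` and `audio.wav`; `scores.tsv` and
#' `study.json` (metadata; the generator also drops `ground_truth.json`) at
#' the top level.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(study$participants)) {
    for (cond in CONDITIONS) {
      d <- file.path(dir, id, cond)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      cc <- study$participants[[id]][[cond]]
      write_recording(cc$recording, file.path(d, "eeg.tsv"))
      write_event_table(cc$events, file.path(d, "events.tsv"))
      data.table::fwrite(cc$presses, file.path(d, "presses.tsv"), sep = "\t")
      write_wav(cc$audio$waveform, cc$audio$srate_hz,
                file.path(d, "audio.wav"))
    }
  }
  data.table::fwrite(study$scores, file.path(dir, "scores.tsv"), sep = "\t")
  jsonlite::write_json(list(participants = names(study$participants),
                            seed = study$seed,
                            audio_srate_hz = study$audio_srate_hz,
                            eeg_srate_hz = study$eeg_srate_hz),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  truth <- study$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a study from the exchange layout
#'
#' @param dir study directory written by [write_study()] (or assembled by a
#'   converter honoring the same contract).
#' @return a study object consumable by [analyze_study()].
#' @export
read_study <- function(dir) {
  meta_path <- file.path(dir, "study.json")
  if (!file.exists(meta_path)) stop_fmt("no study.json in '%s'", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  participants <- list()
  for (id in meta$participants) {
    conds <- list()
    for (cond in CONDITIONS) {
      d <- file.path(dir, id, cond)
      eeg_path <- file.path(d, "eeg.tsv")
      if (!file.exists(eeg_path))
        stop_fmt("participant %s: missing %s-condition file '%s'",
                 id, cond, eeg_path)
      wav <- read_wav(file.path(d, "audio.wav"))
      conds[[cond]] <- list(
        recording = read_recording(eeg_path),
        events = read_event_table(file.path(d, "events.tsv")),
        presses = as.data.frame(data.table::fread(file.path(d, "presses.tsv"))),
        audio = structure(list(waveform = wav$waveform,
                               srate_hz = wav$srate_hz),
                          class = "audio_track"))
    }
    participants[[id]] <- conds
  }
  scores <- as.data.frame(data.table::fread(file.path(dir, "scores.tsv")))
  structure(list(participants = participants, scores = scores,
                 seed = meta$seed, audio_srate_hz = meta$audio_srate_hz,
                 eeg_srate_hz = meta$eeg_srate_hz),
            class = "synthetic_study")
}

#' Write a study report bundle
#'
#' Writes the trial-amplitude tables, TRF weights and GFP series (TSV),
#' significant/individual windows (JSON), the tidy model-results table and
#' a JSON log of every rejection/exclusion decision.
#'
#' @param report a `study_report` from [analyze_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$amp_tables))
    data.table::fwrite(report$amp_tables[[nm]],
                       file.path(dir, paste0("amplitudes_", nm, ".tsv")),
                       sep = "\t")
  tw <- list()
  for (id in names(report$trf)) {
    for (cond in CONDITIONS) {
      m <- report$trf[[id]][[cond]]
      dt <- data.table::data.table(participant = id, condition = cond,
                                   lag_s = m$lags_s)
      w <- data.table::as.data.table(m$weights)
      data.table::setnames(w, m$labels)
      tw[[paste(id, cond)]] <- cbind(dt, w)
    }
  }
  data.table::fwrite(data.table::rbindlist(tw),
                     file.path(dir, "trf_weights.tsv"), sep = "\t")
  if (!is.null(report$trf_stage$gfp_table))
    data.table::fwrite(report$trf_stage$gfp_table,
                       file.path(dir, "gfp_windows.tsv"), sep = "\t")
  jsonlite::write_json(
    list(significant_windows = report$trf_stage$windows,
         tmax_threshold = report$trf_stage$perm$tmax_threshold,
         individual_windows = report$trf_stage$individual_windows,
         erp_windows = lapply(report$erp, function(p)
           lapply(p, function(a) list(peak_s = a$peak_s,
                                      window = a$window)))),
    file.path(dir, "windows.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  data.table::fwrite(report$results, file.path(dir, "model_results.tsv"),
                     sep = "\t")
  jsonlite::write_json(list(seed = report$config$rng_seed,
                            config = unclass(report$config),
                            log = report$log),
                       file.path(dir, "log.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}

#' Run the full pipeline on an on-disk dataset
#'
#' Reads the study from `in_dir`, analyzes it with `config` and writes the
#' report bundle to `out_dir`. Identical seeds yield identical outputs; any
#' stage failure aborts with the stage name and participant id.
#'
#' @param config a [pipeline_config()].
#' @param in_dir study directory ([write_study()] layout).
#' @param out_dir report directory.
#' @return the `study_report`, invisibly.
#' @export
run_pipeline <- function(config, in_dir, out_dir) {
  study <- read_study(in_dir)
  report <- analyze_study(study, config)
  write_report(report, out_dir)
  invisible(report)
}
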