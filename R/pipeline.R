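#' Simulate a complete two-condition study
#'
#' Generates, for every participant, a stimulus schedule, rendered stereo
#' audio, behavioral responses and a continuous EEG recording for each of
#' the two conditions (narrow, wide), plus per-condition behavioral scores,
#' with participant-level variation around the group ground truth. All
#' randomness derives from `seed`.
#'
#' @param n_participants number of participants.
#' @param truth group-level [ground_truth()].
#' @param n_per_category non-overlapping presentations per stimulus
#'   category (48 for a full-scale run; reduce for fast tests).
#' @param soa_range_s inter-onset interval range (s).
#' @param audio_srate_hz audio sampling rate.
#' @param eeg_srate_hz EEG sampling rate.
#' @param seed integer seed.
#' @param montage montage data.frame.
#' @param marker_delay_s constant latency between the recorded sound marker
#'   and the actual sound presentation: event-table onsets are written as
#'   marker times, `marker_delay_s` before the simulated sound/EEG response
#'   (key presses are real-time and carry no delay).
#' @return list of class `synthetic_study`: `participants` (each with
#'   per-condition `recording`, `events`, `presses`, `audio`), `scores`,
#'   `truth`, `seed`.
#' @export
simulate_study <- function(n_participants, truth = ground_truth(),
                           n_per_category = 48, soa_range_s = c(3, 6),
                           audio_srate_hz = 8000, eeg_srate_hz = 500,
                           seed = 1, montage = default_montage(),
                           marker_delay_s = 0.019) {
  with_seed(seed, {
    seeds <- matrix(sample.int(2^30, n_participants * 7),
                    nrow = n_participants)
    participants <- vector("list", n_participants)
    ids <- sprintf("p%02d", seq_len(n_participants))
    scores <- list()
    for (i in seq_len(n_participants)) {
      pt <- participant_truth(truth, seeds[i, 1])
      conds <- list()
      for (ci in 1:2) {
        cond <- CONDITIONS[ci]
        s_base <- seeds[i, 1 + ci]
        sched <- make_schedule(n_per_category, soa_range_s, cond,
                               seed = s_base)
        sched <- simulate_behavior(sched, truth, seed = s_base + 1,
                                   participant = pt)
        bank <- stimulus_bank(audio_srate_hz)
        audio <- render_audio(sched, bank, seed = s_base + 2)
        env_eeg <- extract_envelope(audio, target_srate_hz = eeg_srate_hz)
        rec <- simulate_eeg(sched, env_eeg, truth, montage,
                            duration_s = max(sched$onset_s) + 2,
                            seed = s_base + 3, srate_hz = eeg_srate_hz,
                            participant = pt)
        presses <- data.frame(onset_s =
                                sort(sched$response_onset_s[!is.na(sched$response_onset_s)]))
        # the event file stores marker times (sound minus the marker delay)
        sched$onset_s <- sched$onset_s - marker_delay_s
        conds[[cond]] <- list(recording = rec, events = sched,
                              presses = presses, audio = audio)
      }
      participants[[i]] <- conds
      scores[[i]] <- simulate_scores(truth, ids[i], seeds[i, 7])
    }
    names(participants) <- ids
    structure(list(participants = participants,
                   scores = do.call(rbind, scores),
                   truth = truth, seed = seed,
                   audio_srate_hz = audio_srate_hz,
                   eeg_srate_hz = eeg_srate_hz),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants x 2 conditions, seed %d\n",
              length(x$participants), x$seed))
  invisible(x)
}

# ---- per-participant analysis stages ---------------------------------------

# ERP analyses performed: target P3 for the alarm and the beep, N1 for the
# pooled irrelevant sounds.
erp_analyses <- function() {
  list(alarm_p3 = list(categories = "alarm", spec = component_spec("P3")),
       beep_p3 = list(categories = "beep", spec = component_spec("P3")),
       irrelevant_n1 = list(categories = c("irrelevant1", "irrelevant2"),
                            spec = component_spec("N1")))
}

# Epochs entering an ERP analysis: the stated categories, non-overlapping
# presentations only, and -- when the category is the condition's target --
# hit trials only. Threshold rejection at config$reject_sd_erp.
erp_condition_epochs <- function(rec, events, categories, config) {
  sel <- events[events$category %in% categories & !events$overlap, ,
                drop = FALSE]
  sel <- sel[!sel$is_target | (!is.na(sel$is_hit) & sel$is_hit), , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  ep <- make_epochs(rec, sel, config$epoch_window_s, config$baseline_s)
  if (dim(ep$data)[1] >= 3) {
    mask <- reject_epochs(ep, config$reject_sd_erp)
    ep <- subset_epochs(ep, which(!mask$rejected))
  }
  ep
}

#' Per-participant ERP stage
#'
#' Classifies hits, epochs each analysis set (non-overlapping trials; hits
#' only for targets), rejects artifact epochs, derives the individualized
#' component window from the condition- and channel-averaged waveform and
#' extracts trial-level window means.
#'
#' @param conds per-condition lists with `recording` (preprocessed),
#'   `events` (delay-corrected), `presses`.
#' @param config a [pipeline_config()].
#' @param participant participant id.
#' @return list per analysis: `window`, `peak_s`, `amplitudes` (long table).
#' @export
participant_erp_stage <- function(conds, config, participant = NA) {
  for (cond in CONDITIONS) {
    conds[[cond]]$events <- classify_hits(conds[[cond]]$events,
                                          conds[[cond]]$presses,
                                          config$hit_window_s)
  }
  out <- list()
  for (nm in names(erp_analyses())) {
    an <- erp_analyses()[[nm]]
    eps <- lapply(CONDITIONS, function(cond)
      erp_condition_epochs(conds[[cond]]$recording, conds[[cond]]$events,
                           an$categories, config))
    names(eps) <- CONDITIONS
    if (is.null(eps$narrow) || is.null(eps$wide)) {
      out[[nm]] <- NULL
      next
    }
    wav <- mean_erp_for_peaks(eps$narrow, eps$wide, an$spec$channels)
    win <- withCallingHandlers(
      find_component_window(wav, an$spec),
      warning = function(w) invokeRestart("muffleWarning"))
    amps <- do.call(rbind, lapply(CONDITIONS, function(cond)
      trial_window_means(eps[[cond]], win$window, an$spec$channels,
                         participant)))
    out[[nm]] <- list(window = win$window, peak_s = win$peak_s,
                      amplitudes = amps,
                      n_trials = vapply(eps, function(e) dim(e$data)[1],
                                        numeric(1)))
  }
  out
}

#' Per-participant TRF stage
#'
#' Scales the preprocessed EEG by the configured normalization factor,
#' excises all alarm and beep responses, equalizes total lengths between
#' conditions, fits the ridge forward model per condition and baseline
#' corrects it over the configured lag window.
#'
#' @param conds per-condition lists with preprocessed `recording`,
#'   delay-corrected `events`, and `envelope` on the analysis grid.
#' @param config a [pipeline_config()].
#' @return list(narrow, wide) of baseline-corrected `trf_model`s.
#' @export
participant_trf_stage <- function(conds, config) {
  segs <- lapply(CONDITIONS, function(cond) {
    cc <- conds[[cond]]
    ss <- excise_targets(cc$recording, cc$envelope, cc$events)
    scale_eeg(ss, config$trf_scale)
  })
  names(segs) <- CONDITIONS
  segs <- equalize_lengths(segs$narrow, segs$wide, config$equalize_tol_s)
  trfs <- lapply(segs, function(s) {
    m <- fit_forward_trf(s, config$trf_lags_s, config$trf_lambda)
    baseline_trf(m, config$trf_baseline_s)
  })
  trfs
}

# ---- group-level TRF analysis ----------------------------------------------

#' Group TRF analysis: permutation windows, GFP, individual windows, LMMs
#'
#' Averages each participant's two condition TRFs, locates the
#' condition-independent significant lag windows with the max-t sign-flip
#' permutation test, computes per-condition GFP series, derives each
#' participant's FWHM window around the condition-averaged GFP peak within
#' each significant window, and fits the per-window GFP mixed model.
#'
#' @param trfs_by_participant named list; each element a list(narrow, wide)
#'   of baseline-corrected `trf_model`s.
#' @param config a [pipeline_config()].
#' @return list of class `trf_group_stage`: `perm`, `windows`, `gfps`,
#'   `individual_windows`, `gfp_table`, `fits`, `icc`.
#' @export
trf_group_stage <- function(trfs_by_participant, config = pipeline_config()) {
  avg <- lapply(trfs_by_participant, function(tc) {
    m <- tc$narrow
    m$weights <- (tc$narrow$weights + tc$wide$weights) / 2
    m
  })
  perm <- tmax_windows(avg, test_range_s = config$trf_test_window_s,
                       alpha = config$alpha, n_perm = config$n_permutations,
                       seed = config$rng_seed)
  gfps <- lapply(trfs_by_participant, function(tc)
    list(narrow = gfp(tc$narrow), wide = gfp(tc$wide)))
  lags <- trfs_by_participant[[1]]$narrow$lags_s
  iw <- list()
  if (nrow(perm$windows)) {
    for (w in seq_len(nrow(perm$windows))) {
      sw <- c(perm$windows$t0_s[w], perm$windows$t1_s[w])
      iw[[w]] <- lapply(gfps, function(g)
        individual_fwhm_window(g$narrow, g$wide, sw, lags_s = lags))
    }
  }
  stage <- list(perm = perm, windows = perm$windows, gfps = gfps,
                individual_windows = iw, lags_s = lags)
  stage$gfp_table <- build_gfp_table(stage)
  if (!is.null(stage$gfp_table) && nrow(stage$gfp_table)) {
    stage$fits <- lapply(split(stage$gfp_table, stage$gfp_table$window),
                         fit_lmm_gfp)
    stage$icc <- lapply(split(stage$gfp_table, stage$gfp_table$window),
                        function(dw) icc(dw, "gfp", "participant"))
  }
  structure(stage, class = "trf_group_stage")
}

# Long per-participant, per-condition, per-window GFP means, using either
# each participant's individual FWHM window or the fixed group window.
build_gfp_table <- function(stage, fixed_windows = FALSE,
                            exclude = character(0)) {
  if (!nrow(stage$windows)) return(NULL)
  rows <- list()
  ids <- setdiff(names(stage$gfps), exclude)
  for (w in seq_len(nrow(stage$windows))) {
    sw <- c(stage$windows$t0_s[w], stage$windows$t1_s[w])
    for (id in ids) {
      win <- if (fixed_windows) sw else stage$individual_windows[[w]][[id]]$window
      m <- window_gfp_means(stage$gfps[[id]], win, lags_s = stage$lags_s)
      rows[[length(rows) + 1]] <- data.frame(
        participant = id, condition = names(m), window = w,
        gfp = as.numeric(m), win_lo_s = win[1], win_hi_s = win[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# ---- whole-study analysis ---------------------------------------------------

#' Analyze a (synthetic or loaded) study end to end
#'
#' Runs preprocessing, the ERP stage, the TRF stage and the statistical
#' stage for every participant of a study object, and assembles trial
#' amplitude tables, TRF group results, behavioral models and a tidy
#' results table. Deterministic given `config$rng_seed`.
#'
#' @param study a `synthetic_study` or an object with the same shape
#'   (as produced by [read_study()]).
#' @param config a [pipeline_config()].
#' @param ocular_hook optional replacement artifact-removal function.
#' @param verbose print stage progress.
#' @return list of class `study_report`.
#' @export
analyze_study <- function(study, config = pipeline_config(),
                          ocular_hook = NULL, verbose = FALSE) {
  ids <- names(study$participants)
  erp_out <- list(); trf_out <- list(); behav <- list(); log <- list()
  for (id in ids) {
    conds <- study$participants[[id]]
    for (cond in CONDITIONS) {
      if (is.null(conds[[cond]]))
        stop_fmt("participant %s: missing %s condition", id, cond)
    }
    stage <- tryCatch({
      # joint bad-channel flags across both conditions
      bads <- unique(unlist(lapply(CONDITIONS, function(cc)
        flag_bad_channels(conds[[cc]]$recording))))
      for (cond in CONDITIONS) {
        cc <- conds[[cond]]
        cc$recording <- preprocess_recording(cc$recording, config, bads,
                                             ocular_hook)
        cc$events <- correct_marker_delay(cc$events, config$marker_delay_s)
        if (!is.null(cc$audio))
          cc$envelope <- extract_envelope(cc$audio,
                                          target_srate_hz = config$target_srate_hz)
        conds[[cond]] <- cc
      }
      list(conds = conds, bads = bads)
    }, error = function(e)
      stop_fmt("stage preprocess failed for participant %s: %s", id,
               conditionMessage(e)))
    conds <- stage$conds
    log[[id]] <- list(bads = stage$bads)
    erp_out[[id]] <- tryCatch(
      participant_erp_stage(conds, config, id),
      error = function(e)
        stop_fmt("stage erp failed for participant %s: %s", id,
                 conditionMessage(e)))
    trf_out[[id]] <- tryCatch(
      participant_trf_stage(conds, config),
      error = function(e)
        stop_fmt("stage trf failed for participant %s: %s", id,
                 conditionMessage(e)))
    # behavioral rows: every target with hit flag; RTs for hits
    behav[[id]] <- do.call(rbind, lapply(CONDITIONS, function(cond) {
      ev <- classify_hits(conds[[cond]]$events, conds[[cond]]$presses,
                          config$hit_window_s)
      tg <- ev[ev$is_target, , drop = FALSE]
      if (!nrow(tg)) return(NULL)
      data.frame(participant = id, condition = cond,
                 is_hit = tg$is_hit,
                 rt_s = tg$response_onset_s - tg$onset_s,
                 stringsAsFactors = FALSE)
    }))
    if (verbose) message("analyzed ", id)
  }

  # group ERP models + ICC
  amp_tables <- list(); erp_fits <- list(); erp_icc <- list()
  for (nm in names(erp_analyses())) {
    tabs <- lapply(erp_out, function(p) p[[nm]]$amplitudes)
    tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
    if (is.null(tab) || !nrow(tab)) next
    amp_tables[[nm]] <- tab
    erp_fits[[nm]] <- fit_lmm_amplitude(tab)
    erp_icc[[nm]] <- icc(tab, "amplitude_uv", c("participant", "channel"))
  }

  trf_stage <- trf_group_stage(trf_out, config)

  behav_tab <- do.call(rbind, behav)
  hit_fit <- fit_glmm_hit(behav_tab)
  rts <- behav_tab[!is.na(behav_tab$rt_s), , drop = FALSE]
  rt_fit <- fit_glmm_rt(rts)

  score_fits <- lapply(split(study$scores, study$scores$score_name),
                       fit_score_lmm)

  trf_fits <- trf_stage$fits %||% list()
  if (length(trf_fits))
    names(trf_fits) <- paste0("trf_gfp_w", names(trf_fits))
  results <- c(erp_fits, trf_fits,
               list(hit_rate = hit_fit, reaction_time = rt_fit),
               stats::setNames(score_fits, paste0("score_", names(score_fits))))

  structure(list(
    config = config, erp = erp_out, erp_fits = erp_fits, erp_icc = erp_icc,
    amp_tables = amp_tables, trf = trf_out, trf_stage = trf_stage,
    behavior = behav_tab, hit_fit = hit_fit, rt_fit = rt_fit,
    score_fits = score_fits, results = tidy_results(results), log = log),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  participants: %d; ERP analyses: %s\n", length(x$erp),
              paste(names(x$erp_fits), collapse = ", ")))
  cat(sprintf("  TRF significant windows: %d\n", nrow(x$trf_stage$windows)))
  print(x$results, digits = 3)
  invisible(x)
}
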