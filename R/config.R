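#' Pipeline configuration
#'
#' Bundles every tunable analysis parameter with the defaults of the study
#' design: 0.1 Hz high-pass and 30 Hz low-pass passband edges (Hamming FIR),
#' resampling to 250 Hz, a constant 19 ms sound-marker delay, -200..800 ms
#' epochs with -200..0 ms baseline, 2 SD (continuous cleaning) and 3 SD (ERP)
#' rejection thresholds, a 3 s hit window, TRF lags -200..800 ms with ridge
#' lambda 0.1 and EEG scaling factor 0.0313, a 0..450 ms permutation test
#' range with -100..0 ms TRF baseline, alpha 0.05 and 2000 sign-flip
#' permutations.
#'
#' @param hp_edge_hz high-pass passband edge (Hz).
#' @param lp_edge_hz low-pass passband edge (Hz).
#' @param target_srate_hz analysis sampling rate after resampling (Hz).
#' @param marker_delay_s constant delay added to every stimulus onset (s).
#' @param epoch_window_s ERP epoch window, seconds relative to onset.
#' @param baseline_s ERP baseline window (s).
#' @param reject_sd_ica threshold (SDs) for continuous-cleaning epoch rejection.
#' @param reject_sd_erp threshold (SDs) for ERP epoch rejection.
#' @param hit_window_s a press within this many seconds after a target is a hit.
#' @param trf_lags_s TRF lag range (s).
#' @param trf_lambda ridge penalty for the forward model.
#' @param trf_scale multiplicative EEG normalization before TRF fitting.
#' @param trf_test_window_s lag range for the permutation test (s).
#' @param trf_baseline_s lag window for TRF baseline correction (s).
#' @param alpha significance level.
#' @param n_permutations sign-flip permutations for the max-t test.
#' @param equalize_tol_s maximum allowed total-length difference between
#'   conditions after TRF segment equalization (s).
#' @param rng_seed integer seed recorded in the report and used for all
#'   stochastic stages.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(hp_edge_hz = 0.1,
                            lp_edge_hz = 30,
                            target_srate_hz = 250,
                            marker_delay_s = 0.019,
                            epoch_window_s = c(-0.2, 0.8),
                            baseline_s = c(-0.2, 0),
                            reject_sd_ica = 2,
                            reject_sd_erp = 3,
                            hit_window_s = 3.0,
                            trf_lags_s = c(-0.2, 0.8),
                            trf_lambda = 0.1,
                            trf_scale = 0.0313,
                            trf_test_window_s = c(0, 0.45),
                            trf_baseline_s = c(-0.1, 0),
                            alpha = 0.05,
                            n_permutations = 2000,
                            equalize_tol_s = 60,
                            rng_seed = 1L) {
  cfg <- list(
    hp_edge_hz = hp_edge_hz, lp_edge_hz = lp_edge_hz,
    target_srate_hz = target_srate_hz, marker_delay_s = marker_delay_s,
    epoch_window_s = as.numeric(epoch_window_s),
    baseline_s = as.numeric(baseline_s),
    reject_sd_ica = reject_sd_ica, reject_sd_erp = reject_sd_erp,
    hit_window_s = hit_window_s, trf_lags_s = as.numeric(trf_lags_s),
    trf_lambda = trf_lambda, trf_scale = trf_scale,
    trf_test_window_s = as.numeric(trf_test_window_s),
    trf_baseline_s = as.numeric(trf_baseline_s),
    alpha = alpha, n_permutations = as.integer(n_permutations),
    equalize_tol_s = equalize_tol_s, rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pairs <- c("epoch_window_s", "baseline_s", "trf_lags_s",
             "trf_test_window_s", "trf_baseline_s")
  for (p in pairs) {
    w <- cfg[[p]]
    if (length(w) != 2 || !all(is.finite(w)) || w[1] >= w[2])
      stop_fmt("config window '%s' must be an ordered (low, high) pair", p)
  }
  pos <- c("hp_edge_hz", "lp_edge_hz", "target_srate_hz", "hit_window_s",
           "trf_lambda", "trf_scale", "reject_sd_ica", "reject_sd_erp",
           "equalize_tol_s")
  for (p in pos) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0)
      stop_fmt("config parameter '%s' must be positive", p)
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_fmt("alpha must be in (0, 1)")
  if (cfg$n_permutations < 1) stop_fmt("n_permutations must be >= 1")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  filters: %.3g-%.3g Hz (Hamming FIR), resample %g Hz\n",
              x$hp_edge_hz, x$lp_edge_hz, x$target_srate_hz))
  cat(sprintf("  epochs: [%g, %g] s, baseline [%g, %g] s, reject %g/%g SD\n",
              x$epoch_window_s[1], x$epoch_window_s[2],
              x$baseline_s[1], x$baseline_s[2],
              x$reject_sd_ica, x$reject_sd_erp))
  cat(sprintf("  TRF: lags [%g, %g] s, lambda %g, scale %g, test [%g, %g] s\n",
              x$trf_lags_s[1], x$trf_lags_s[2], x$trf_lambda, x$trf_scale,
              x$trf_test_window_s[1], x$trf_test_window_s[2]))
  cat(sprintf("  permutations: %d at alpha %g, seed %d\n",
              x$n_permutations, x$alpha, x$rng_seed))
  invisible(x)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`; `write_config` its path,
#'   invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
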