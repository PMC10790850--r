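#' Parameter-recovery experiments
#'
#' Seeded, self-contained validation experiments that exercise the analysis
#' machinery against the generator's known ground truth. Each function runs
#' one replicate and returns the measured quantities; callers loop over
#' seeds to estimate pass rates. These back the package's acceptance
#' checks and are also useful when tuning a study design.
#'
#' `kernel_recovery_run` simulates an envelope-only recording (no discrete
#' events) driven by a broadband probe envelope at the default
#' signal-to-noise ratio, fits the ridge forward TRF at the standard
#' settings, and correlates the topography-weighted recovered kernel with
#' the injected one over lags 0-0.45 s.
#'
#' @param seed integer seed for the replicate.
#' @param duration_s length of the simulated recording.
#' @param truth a [ground_truth()].
#' @return correlation between recovered and injected kernel.
#' @export
kernel_recovery_run <- function(seed, duration_s = 240,
                                truth = ground_truth()) {
  montage <- default_montage()
  topo <- midpoint_topography(montage, c("Fz", "Cz"), 0.8)
  with_seed(seed, {
    n5 <- duration_s * 500
    env5 <- pmax(0, 0.05 + one_over_f_noise(n5, 500, alpha = 0.3,
                                            sd_target = 0.02))
    rec <- simulate_eeg(empty_events(), list(values = env5, srate_hz = 500),
                        truth, montage, duration_s = duration_s,
                        seed = sample.int(2^30, 1), srate_hz = 500)
    rec2 <- resample_recording(rec, 250)
    env2 <- as.numeric(resample_rows(matrix(env5, 1), 500, 250))
    n <- min(ncol(rec2$data), length(env2))
    segs <- structure(list(
      segments = list(list(eeg = rec2$data[, seq_len(n)] * 0.0313,
                           env = env2[seq_len(n)])),
      srate_hz = 250, total_s = n / 250, starts_s = 0,
      labels = rec2$labels, scale_applied = 0.0313),
      class = "segment_set")
    m <- baseline_trf(fit_forward_trf(segs, c(-0.2, 0.8), 0.1), c(-0.1, 0))
    k <- true_trf_kernel(truth, "narrow", 250, c(0, 0.45))
    li <- m$lags_s >= 0 & m$lags_s <= 0.45 + 1e-9
    wavg <- as.numeric(m$weights[li, ] %*% topo[m$labels]) / sum(topo^2)
    stats::cor(wavg, k$values)
  })
}

#' @rdname kernel_recovery_run
#'
#' @details `tmax_null_run` draws pure-noise participant TRFs and reports
#' whether the max-t sign-flip permutation test declares any lag
#' significant -- a family-wise false positive under the null.
#'
#' @param n_participants,n_channels null-simulation dimensions.
#' @param n_perm sign-flip permutations.
#' @param alpha family-wise level.
#' @return `tmax_null_run`: TRUE when any (spurious) window is detected.
#' @export
tmax_null_run <- function(seed, n_participants = 15, n_channels = 8,
                          n_perm = 500, alpha = 0.05) {
  lags <- seq.int(-50, 200) / 250
  with_seed(seed, {
    arr <- array(stats::rnorm(n_participants * 251 * n_channels),
                 c(n_participants, 251, n_channels))
    res <- tmax_windows(arr, lags_s = lags, test_range_s = c(-0.2, 0.8),
                        alpha = alpha, n_perm = n_perm,
                        seed = sample.int(2^30, 1))
    nrow(res$windows) > 0
  })
}

#' @rdname kernel_recovery_run
#'
#' @details `endtoend_recovery_run` simulates a complete reduced-size
#' two-condition study, runs the full pipeline, and reports the four
#' study-level contrasts with their p-values: the alarm and beep P3
#' condition effects (wide minus narrow), the GFP contrast in the
#' significant lag window that overlaps the late test range the most, and
#' the hit-rate condition effect on the logit scale.
#'
#' @param n_per_category presentations per stimulus category (reduced
#'   study size).
#' @param n_permutations permutations for the window search.
#' @param audio_srate_hz audio rate of the reduced study.
#' @return `endtoend_recovery_run`: list of per-contrast `estimate`/`p`
#'   plus a `pass` flag (all signs correct at p < 0.05).
#' @export
endtoend_recovery_run <- function(seed, n_participants = 20,
                                  n_per_category = 12, n_permutations = 400,
                                  audio_srate_hz = 1000) {
  study <- simulate_study(n_participants, n_per_category = n_per_category,
                          audio_srate_hz = audio_srate_hz, seed = seed)
  cfg <- pipeline_config(n_permutations = n_permutations, rng_seed = seed)
  rep <- suppressWarnings(analyze_study(study, cfg))
  rc <- rep$results[rep$results$term == "cond", ]
  pick <- function(model) {
    i <- match(model, rc$model)
    list(estimate = rc$estimate[i], p = rc$p[i])
  }
  out <- list(alarm_p3 = pick("alarm_p3"), beep_p3 = pick("beep_p3"),
              hit_rate = pick("hit_rate"))
  w <- rep$trf_stage$windows
  if (nrow(w)) {
    overlap <- pmin(w$t1_s, 0.448) - pmax(w$t0_s, 0.216)
    late <- which.max(overlap)
    out$late_gfp <- pick(paste0("trf_gfp_w", late))
    out$late_window <- c(w$t0_s[late], w$t1_s[late])
  } else {
    out$late_gfp <- list(estimate = NA_real_, p = NA_real_)
  }
  out$pass <- isTRUE(out$alarm_p3$estimate < 0 && out$alarm_p3$p < 0.05 &&
                       out$beep_p3$estimate > 0 && out$beep_p3$p < 0.05 &&
                       out$late_gfp$estimate > 0 && out$late_gfp$p < 0.05 &&
                       out$hit_rate$estimate < 0 && out$hit_rate$p < 0.05)
  out
}

#' @rdname kernel_recovery_run
#'
#' @details `gfp_coverage_run` simulates one well-specified random-intercept
#' data set (participant intercept SD 1, residual SD 0.7, condition effect
#' 0.8), fits the GFP mixed model, and reports whether the 95% confidence
#' interval covers the true effect.
#'
#' @param effect true condition effect of the coverage simulation.
#' @return `gfp_coverage_run`: TRUE when the 95% CI covers the truth.
#' @export
gfp_coverage_run <- function(seed, n_participants = 20, effect = 0.8) {
  with_seed(seed, {
    d <- data.frame(
      participant = rep(sprintf("p%02d", seq_len(n_participants)), 2),
      condition = rep(c("narrow", "wide"), each = n_participants))
    u <- stats::rnorm(n_participants, 0, 1)
    d$gfp <- 5.57 + effect * (d$condition == "wide") +
      u[as.integer(factor(d$participant))] +
      stats::rnorm(nrow(d), 0, 0.7)
    f <- fit_lmm_gfp(d)
    co <- f$coefficients
    i <- match("cond", co$term)
    co$ci_lo[i] <= effect && effect <= co$ci_hi[i]
  })
}
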