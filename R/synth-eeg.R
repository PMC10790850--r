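#' Ground-truth parameters of the synthetic study
#'
#' Collects every hidden parameter of the generator so that recovery tests
#' can compare estimates against the truth. ERP generators are sums of
#' Gaussian-windowed lobes: a frontocentral N1 (~100 ms, negative) and P2
#' (~200 ms) and a parietal P3 (~350 ms) whose amplitude grows by
#' `p3_target_gain` microvolts when the stimulus is the condition's target.
#' The whole-soundscape response is a lag-domain TRF kernel with three lobes
#' (~60, 150, 320 ms; negative/positive/negative) applied to the z-scored
#' audio envelope; under a wide attentional focus the late lobe is scaled by
#' `wide_gain`. Noise is 1/f with stereotyped blink artifacts. Behavior:
#' targets are hit with a condition-dependent probability and hit reaction
#' times are inverse-Gaussian.
#'
#' Default effect sizes are set to the magnitudes typical of this paradigm:
#' a 4 microvolt P3 target effect, a 1.5-fold late-lobe gain, hit
#' probabilities 0.962 (narrow) vs. 0.68 (wide), mean RTs ~0.81 s.
#'
#' @param p3_target_gain target-related P3 amplitude increase (microvolts).
#' @param wide_gain multiplicative gain of the late TRF lobe in the wide
#'   condition (>= 1).
#' @param noise_alpha spectral exponent of the 1/f background noise.
#' @param noise_sd_uv noise standard deviation per channel (microvolts).
#' @param blink_rate_hz Poisson rate of blink artifacts.
#' @param blink_amp_uv blink amplitude at the most frontal sites.
#' @param hit_prob named per-condition probability of detecting a target.
#' @param rt_mu_s,rt_lambda_s inverse-Gaussian RT mean and shape per condition.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(p3_target_gain = 4,
                         wide_gain = 1.5,
                         noise_alpha = 1,
                         noise_sd_uv = 8,
                         blink_rate_hz = 0.15,
                         blink_amp_uv = 120,
                         hit_prob = c(narrow = 0.962, wide = 0.68),
                         rt_mu_s = c(narrow = 0.814, wide = 0.81),
                         rt_lambda_s = c(narrow = 3, wide = 3)) {
  stopifnot(all(hit_prob >= 0 & hit_prob <= 1), wide_gain >= 1,
            all(rt_mu_s > 0), all(rt_lambda_s > 0), noise_sd_uv >= 0)
  erp <- list(
    #               n1_amp n1_lat n1_sd p2_amp p3_amp
    alarm       = list(n1 = c(-8.0, 0.100, 0.020), p2 = c(5.0, 0.200, 0.030),
                       p3 = c(2.0, 0.350, 0.060)),
    beep        = list(n1 = c(-2.0, 0.100, 0.040), p2 = c(0.0, 0.200, 0.030),
                       p3 = c(0.0, 0.350, 0.060)),
    irrelevant1 = list(n1 = c(-7.8, 0.100, 0.020), p2 = c(5.0, 0.200, 0.030),
                       p3 = c(0.5, 0.350, 0.060)),
    irrelevant2 = list(n1 = c(-7.8, 0.100, 0.020), p2 = c(5.0, 0.200, 0.030),
                       p3 = c(0.5, 0.350, 0.060)),
    instruction = list(n1 = c(-3.0, 0.100, 0.025), p2 = c(2.0, 0.200, 0.030),
                       p3 = c(0.5, 0.350, 0.060))
  )
  # lobe gains are integrated (microvolt x second per unit z-scored
  # envelope); sized so the envelope-driven response is ~2.5-3 microvolts,
  # i.e. a 10-15% share of channel variance against the default noise
  trf <- list(lat_s = c(0.060, 0.150, 0.320),
              sd_s = c(0.025, 0.040, 0.080),
              amp_uv = c(-25, 32.5, -25),
              late_lobe = 3L)
  scores <- list(workload = c(narrow = 60.6, wide = 71.45, sd_participant = 10,
                              sd_resid = 10),
                 layers = c(narrow = 20, wide = 18.6, sd_participant = 4,
                            sd_resid = 2.4),
                 instructions = c(narrow = 44, wide = 43.2, sd_participant = 3,
                                  sd_resid = 2))
  between <- list(amp_scale_sdlog = 0.2, lat_jitter_sd_s = 0.010,
                  hit_logit_sd = 0.5, rt_mu_sdlog = 0.08)
  structure(list(erp = erp, p3_target_gain = p3_target_gain, trf = trf,
                 wide_gain = wide_gain, noise_alpha = noise_alpha,
                 noise_sd_uv = noise_sd_uv, blink_rate_hz = blink_rate_hz,
                 blink_amp_uv = blink_amp_uv, hit_prob = hit_prob,
                 rt_mu_s = rt_mu_s, rt_lambda_s = rt_lambda_s,
                 scores = scores, between = between),
            class = "ground_truth")
}

gauss_lobe <- function(t, amp, lat, sd) amp * exp(-(t - lat)^2 / (2 * sd^2))

# Frontocentral (N1+P2) and parietal (P3) source kernels for one event,
# sampled on t = 0 .. 0.7 s.
erp_kernels <- function(category, is_target, truth, srate,
                        amp_scale = 1, lat_shift = 0) {
  t <- seq(0, 0.7, by = 1 / srate)
  k <- truth$erp[[category]]
  p3_amp <- k$p3[1] + if (is_target) truth$p3_target_gain else 0
  list(
    fc = amp_scale * (gauss_lobe(t, k$n1[1], k$n1[2] + lat_shift, k$n1[3]) +
                        gauss_lobe(t, k$p2[1], k$p2[2] + lat_shift, k$p2[3])),
    p = amp_scale * gauss_lobe(t, p3_amp, k$p3[2] + lat_shift, k$p3[3])
  )
}

#' The injected TRF kernel on a lag grid
#'
#' @param truth a `ground_truth`.
#' @param condition `"narrow"` or `"wide"` (scales the late lobe).
#' @param srate_hz sampling rate of the lag grid.
#' @param lags_s lag range.
#' @param amp_scale per-participant amplitude multiplier.
#' @return list(lags_s, values) in microvolts per unit envelope.
#' @export
true_trf_kernel <- function(truth, condition = "narrow", srate_hz = 500,
                            lags_s = c(0, 0.5), amp_scale = 1) {
  lags <- seq(round(lags_s[1] * srate_hz),
              round(lags_s[2] * srate_hz)) / srate_hz
  amp <- truth$trf$amp_uv
  if (condition == "wide") amp[truth$trf$late_lobe] <-
      amp[truth$trf$late_lobe] * truth$wide_gain
  v <- rowSums(mapply(function(a, l, s) gauss_lobe(lags, a, l, s),
                      amp, truth$trf$lat_s, truth$trf$sd_s))
  list(lags_s = lags, values = amp_scale * v)
}

# Per-participant realization of the group ground truth.
participant_truth <- function(truth, seed = NULL) {
  with_seed(seed, {
    b <- truth$between
    list(
      amp_scale = exp(stats::rnorm(1, 0, b$amp_scale_sdlog)),
      lat_shift = stats::rnorm(1, 0, b$lat_jitter_sd_s),
      hit_logit_shift = stats::rnorm(1, 0, b$hit_logit_sd),
      rt_mu_scale = exp(stats::rnorm(1, 0, b$rt_mu_sdlog))
    )
  })
}

#' Simulate a continuous EEG recording for one run
#'
#' EEG = sum of event ERP kernels projected through fixed Gaussian
#' topographies (frontocentral for N1/P2, parietal for P3), plus the
#' condition-specific TRF kernel convolved with the z-scored audio envelope
#' (frontocentral topography), plus 1/f noise per channel and stereotyped
#' blink artifacts at frontal sites.
#'
#' @param schedule event table (its `condition` selects the TRF kernel and
#'   `is_target` the P3 gain).
#' @param audio_envelope numeric vector at `srate_hz`, or a list with
#'   `values`/`srate_hz` (resampled by linear interpolation if needed); NULL
#'   for no envelope-driven response.
#' @param truth a [ground_truth()].
#' @param montage montage data.frame; default [default_montage()].
#' @param duration_s recording length; must exceed the last event + 1 s.
#' @param seed integer seed.
#' @param srate_hz sampling rate (500 Hz by default).
#' @param participant per-participant realization from `participant_truth`;
#'   NULL for the group mean.
#' @return an [new_recording()] object, reference "Fz".
#' @export
simulate_eeg <- function(schedule, audio_envelope, truth,
                         montage = default_montage(), duration_s = NULL,
                         seed = NULL, srate_hz = 500, participant = NULL) {
  if (is.null(duration_s)) {
    duration_s <- if (nrow(schedule)) max(schedule$onset_s) + 2 else 10
  }
  if (nrow(schedule) && duration_s < max(schedule$onset_s) + 1)
    stop_fmt("duration %.3g s is shorter than last event + 1 s", duration_s)
  n <- round(duration_s * srate_hz)
  nch <- nrow(montage)
  pt <- participant %||% list(amp_scale = 1, lat_shift = 0)
  condition <- if (nrow(schedule)) schedule$condition[1] else "narrow"

  src_fc <- numeric(n); src_p <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    kk <- erp_kernels(schedule$category[i], schedule$is_target[i], truth,
                      srate_hz, pt$amp_scale, pt$lat_shift)
    i0 <- sample_at(schedule$onset_s[i], srate_hz)
    idx <- i0:min(n, i0 + length(kk$fc) - 1L)
    ki <- seq_along(idx)
    src_fc[idx] <- src_fc[idx] + kk$fc[ki]
    src_p[idx] <- src_p[idx] + kk$p[ki]
  }

  src_trf <- numeric(n)
  if (!is.null(audio_envelope)) {
    env <- audio_envelope
    if (is.list(env)) {
      if (abs(env$srate_hz - srate_hz) > 1e-9) {
        t_in <- (seq_along(env$values) - 1) / env$srate_hz
        env <- stats::approx(t_in, env$values, xout = (seq_len(n) - 1) / srate_hz,
                             rule = 2)$y
      } else env <- env$values
    }
    if (length(env) < n) env <- c(env, rep(env[length(env)], n - length(env)))
    env <- env[seq_len(n)]
    if (stats::sd(env) > 0) env <- (env - mean(env)) / stats::sd(env)
    # kernel amplitudes are continuous-time gains (microvolts per unit
    # envelope, integrated over lag time), so the discrete convolution is
    # scaled by the sample interval
    k <- true_trf_kernel(truth, condition, srate_hz,
                         amp_scale = pt$amp_scale)$values
    src_trf <- fft_filter(env, k)[seq_len(n)] / srate_hz
  }

  topo_fc <- midpoint_topography(montage, c("Fz", "Cz"), 0.8)
  topo_p <- gaussian_topography(montage, "Pz", 0.9)
  topo_blink <- {
    w <- midpoint_topography(montage, c("Fp1", "Fp2"), 0.5)
    w / max(w)
  }

  with_seed(seed, {
    data <- cbind(topo_fc, topo_p) %*% rbind(src_fc + src_trf, src_p)
    if (truth$noise_sd_uv > 0) {
      data <- data + one_over_f_noise_rows(n, nch, srate_hz,
                                           truth$noise_alpha,
                                           truth$noise_sd_uv)
    }
    if (truth$blink_rate_hz > 0 && truth$blink_amp_uv > 0) {
      n_blinks <- stats::rpois(1, truth$blink_rate_hz * duration_s)
      if (n_blinks > 0) {
        tmpl <- truth$blink_amp_uv *
          sin(pi * seq(0, 1, by = 1 / (0.35 * srate_hz)))^2
        at <- sort(stats::runif(n_blinks, 0, duration_s - 0.4))
        src_b <- numeric(n)
        for (tb in at) {
          i0 <- sample_at(tb, srate_hz)
          idx <- i0:min(n, i0 + length(tmpl) - 1L)
          src_b[idx] <- src_b[idx] + tmpl[seq_along(idx)]
        }
        data <- data + outer(topo_blink, src_b)
      }
    }
    new_recording(data, srate_hz, montage$label, montage,
                  reference = "Fz")
  })
}
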