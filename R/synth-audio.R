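#' Synthetic stimulus bank
#'
#' Deterministic source waveforms for the five discrete stimulus categories:
#' a long, loud two-harmonic alarm tone; a short, quiet beep; a noise burst
#' and a frequency sweep as the two irrelevant monitor-like sounds; and a
#' speech-like amplitude-modulated harmonic complex as the spoken
#' instruction. All carriers stay below 900 Hz so the bank remains valid at
#' low test sampling rates.
#'
#' @param srate_hz audio sampling rate (default 8000; tests may use less).
#' @return list with `srate_hz` and a named list `stimuli` of mono waveforms.
#' @export
stimulus_bank <- function(srate_hz = 8000) {
  pars <- stimulus_params()
  tt <- function(d) seq(0, d - 1 / srate_hz, by = 1 / srate_hz)
  ramp <- function(x, r_s = 0.01) {
    n <- length(x); nr <- max(1L, round(r_s * srate_hz))
    e <- rep(1, n)
    e[seq_len(nr)] <- seq(0, 1, length.out = nr)
    e[n - seq_len(nr) + 1L] <- seq(0, 1, length.out = nr)
    x * e
  }
  d <- stats::setNames(pars$duration_s, pars$category)
  t_a <- tt(d[["alarm"]]); t_b <- tt(d[["beep"]])
  t_i1 <- tt(d[["irrelevant1"]]); t_i2 <- tt(d[["irrelevant2"]])
  t_in <- tt(d[["instruction"]])
  set.seed(20260901)  # bank waveforms are fixed material, not per-run draws
  noise1 <- stats::filter(stats::rnorm(length(t_i1)), rep(1 / 6, 6),
                          circular = TRUE)
  am <- 0.6 + 0.4 * sin(2 * pi * 4 * t_in + pi / 3)
  # levels sit a few dB above the continuous bed (cf. a busy room), so the
  # soundscape envelope keeps a realistic dynamic range: the alarm is the
  # loudest discrete stream, the beep clearly the quietest
  stimuli <- list(
    alarm = ramp(0.55 * (0.8 * sin(2 * pi * 620 * t_a) +
                           0.35 * sin(2 * pi * 880 * t_a))),
    beep = ramp(0.16 * sin(2 * pi * 840 * t_b), 0.005),
    irrelevant1 = ramp(0.35 * as.numeric(noise1) / max(abs(noise1))),
    irrelevant2 = ramp(0.35 * sin(2 * pi * (400 * t_i2 + 500 * t_i2^2 / 2))),
    instruction = ramp(0.32 * am * (sin(2 * pi * 150 * t_in) +
                                      0.5 * sin(2 * pi * 300 * t_in) +
                                      0.3 * sin(2 * pi * 450 * t_in)))
  )
  list(srate_hz = srate_hz, stimuli = stimuli)
}

# Constant-power stereo panning gains for an azimuth in degrees
# (+right; values beyond +-90 deg saturate to fully lateral).
pan_gains <- function(az_deg) {
  az <- pmin(90, pmax(-90, az_deg))
  th <- (az + 90) / 180 * (pi / 2)
  c(left = cos(th), right = sin(th))
}

#' Render the scheduled soundscape to stereo audio
#'
#' Mixes a continuous background bed (hospital-machinery-like filtered noise,
#' present on both channels) with every scheduled discrete stimulus, placed
#' at its onset and spatialized by constant-power stereo gain panning of its
#' azimuth. The mix is peak-normalized so clipping cannot occur.
#'
#' @param schedule event table from [make_schedule()].
#' @param bank stimulus bank from [stimulus_bank()].
#' @param seed integer seed for the background bed.
#' @param duration_s total duration; default last offset + 2 s.
#' @param background_level RMS of the background bed.
#' @return list of class `audio_track`: `waveform` (samples x 2, in [-1, 1])
#'   and `srate_hz`.
#' @export
render_audio <- function(schedule, bank, seed = NULL, duration_s = NULL,
                         background_level = 0.15) {
  srate <- bank$srate_hz
  if (is.null(duration_s)) {
    duration_s <- if (nrow(schedule) == 0) 10 else
      max(schedule$onset_s + schedule$duration_s) + 2
  }
  n <- round(duration_s * srate)
  with_seed(seed, {
    bed <- one_over_f_noise_rows(n, 3, srate, alpha = 1.2, sd_target = 1)
    wf <- cbind(
      left = background_level * (0.8 * bed[1, ] + 0.6 * bed[2, ]),
      right = background_level * (0.8 * bed[1, ] + 0.6 * bed[3, ])
    )
    if (nrow(schedule)) {
      miss <- setdiff(unique(schedule$category), names(bank$stimuli))
      if (length(miss))
        stop_fmt("stimulus bank has no waveform for: %s",
                 paste(miss, collapse = ", "))
      for (i in seq_len(nrow(schedule))) {
        s <- bank$stimuli[[schedule$category[i]]]
        i0 <- sample_at(schedule$onset_s[i], srate)
        idx <- i0:(i0 + length(s) - 1L)
        keep <- idx <= n
        g <- pan_gains(schedule$direction_deg[i])
        wf[idx[keep], 1] <- wf[idx[keep], 1] + g[["left"]] * s[keep]
        wf[idx[keep], 2] <- wf[idx[keep], 2] + g[["right"]] * s[keep]
      }
    }
    peak <- max(abs(wf))
    if (peak > 0.99) wf <- wf * (0.99 / peak)
    structure(list(waveform = wf, srate_hz = srate), class = "audio_track")
  })
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track> %d samples x %d ch @ %g Hz (%.1f s), peak %.3f\n",
              nrow(x$waveform), ncol(x$waveform), x$srate_hz,
              nrow(x$waveform) / x$srate_hz, max(abs(x$waveform))))
  invisible(x)
}
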