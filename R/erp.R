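#' Component specifications for the N1 and P3
#'
#' The N1 is quantified as a negative deflection between 50 and 150 ms over
#' frontocentral channels (Fz, FC1, FC2, Cz, C3, C4) with a +-25 ms
#' individualized window; the P3 as a positive deflection between 300 and
#' 400 ms over centroparietal channels (Pz, P3, P4, CPz, CP1, CP2) with a
#' +-50 ms window.
#'
#' @param name `"N1"` or `"P3"`.
#' @return list(name, polarity, search_s, half_width_s, channels).
#' @export
component_spec <- function(name = c("N1", "P3")) {
  name <- match.arg(name)
  if (name == "N1") {
    list(name = "N1", polarity = "negative", search_s = c(0.05, 0.15),
         half_width_s = 0.025,
         channels = c("Fz", "FC1", "FC2", "Cz", "C3", "C4"))
  } else {
    list(name = "P3", polarity = "positive", search_s = c(0.30, 0.40),
         half_width_s = 0.050,
         channels = c("Pz", "P3", "P4", "CPz", "CP1", "CP2"))
  }
}

#' Classify target hits from a key-press log
#'
#' A hit is any space-bar press within `hit_window_s` seconds after a target
#' onset (exclusive at the onset, inclusive at onset + window). Each press is
#' consumed by at most one target: presses are processed in time order and
#' assigned to the earliest not-yet-hit target whose window contains them.
#'
#' @param events event table with `is_target`.
#' @param presses numeric vector of press times, or a data.frame with an
#'   `onset_s` column (need not be sorted; sorted internally).
#' @param hit_window_s response window (s).
#' @return events with `is_hit` (targets only) and `response_onset_s` set
#'   from the consumed press.
#' @export
classify_hits <- function(events, presses, hit_window_s = 3) {
  if (is.data.frame(presses)) presses <- presses$onset_s
  presses <- sort(as.numeric(presses))
  ev <- events
  ev$is_hit <- ifelse(ev$is_target, FALSE, NA)
  ev$response_onset_s <- NA_real_
  tgt <- which(ev$is_target)
  for (p in presses) {
    open <- tgt[!ev$is_hit[tgt] &
                  ev$onset_s[tgt] < p & p <= ev$onset_s[tgt] + hit_window_s]
    if (length(open)) {
      i <- open[1]
      ev$is_hit[i] <- TRUE
      ev$response_onset_s[i] <- p
    }
  }
  ev
}

#' Cut stimulus-locked epochs with baseline correction
#'
#' Epochs span `[tmin, tmax)` seconds around each event onset on a half-open
#' sample grid (the onset sample, at t = 0, is included; 1.0 s at 250 Hz
#' gives exactly 250 samples). The mean over the baseline window is
#' subtracted per trial and channel. Events too close to the recording edge
#' are dropped and listed in the `dropped` attribute.
#'
#' @param rec preprocessed `eeg_recording`.
#' @param events event table (rows become trials, carried as `trial_meta`).
#' @param window (tmin, tmax) epoch window (s).
#' @param baseline (b0, b1) baseline window (s), half-open.
#' @return an `epoch_set`: trials x channels x samples array plus metadata.
#' @export
make_epochs <- function(rec, events, window = c(-0.2, 0.8),
                        baseline = c(-0.2, 0)) {
  srate <- rec$srate_hz
  offs <- seq.int(round(window[1] * srate), round(window[2] * srate) - 1L)
  times <- offs / srate
  n <- ncol(rec$data)
  onset_samp <- sample_at(events$onset_s, srate)
  ok <- onset_samp + offs[1] >= 1 & onset_samp + offs[length(offs)] <= n
  dropped <- which(!ok)
  keep <- which(ok)
  arr <- array(NA_real_, c(length(keep), nrow(rec$data), length(offs)))
  bidx <- which(times >= baseline[1] - 1e-9 & times < baseline[2] - 1e-9)
  for (k in seq_along(keep)) {
    seg <- rec$data[, onset_samp[keep[k]] + offs, drop = FALSE]
    if (length(bidx))
      seg <- seg - rowMeans(seg[, bidx, drop = FALSE])
    arr[k, , ] <- seg
  }
  structure(list(data = arr, times = times, srate_hz = srate,
                 labels = rec$labels, window = window, baseline = baseline,
                 trial_meta = events[keep, , drop = FALSE]),
            class = "epoch_set", dropped = dropped)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate_hz,
              x$window[1], x$window[2]))
  invisible(x)
}

# Subset an epoch_set by trial indices.
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[idx, , drop = FALSE]
  epochs
}

#' Condition-averaged waveform for peak search
#'
#' Averages over trials within each condition, then over the two condition
#' means with equal weight (so unbalanced trial counts do not bias the
#' peak), then over the selected channels.
#'
#' @param epochs_narrow,epochs_wide `epoch_set`s of the two conditions.
#' @param channels channel labels to average.
#' @return numeric waveform with a `times` attribute.
#' @export
mean_erp_for_peaks <- function(epochs_narrow, epochs_wide, channels) {
  for (nm in c("narrow", "wide")) {
    e <- if (nm == "narrow") epochs_narrow else epochs_wide
    if (is.null(e) || dim(e$data)[1] == 0)
      stop_fmt("condition '%s' has no epochs", nm)
  }
  one <- function(e) {
    ic <- match(channels, e$labels)
    if (anyNA(ic)) stop_fmt("channels not present: %s",
                            paste(channels[is.na(ic)], collapse = ", "))
    m <- apply(e$data[, ic, , drop = FALSE], c(2, 3), mean)  # chan x samp
    colMeans(m)
  }
  w <- (one(epochs_narrow) + one(epochs_wide)) / 2
  attr(w, "times") <- epochs_narrow$times
  w
}

#' Individualized component window from a mean waveform
#'
#' Finds the signed extremum (minimum for negative polarity, maximum for
#' positive) within the component's search range; ties resolve to the
#' earliest latency, and a range-edge extremum is accepted with a warning.
#' The window is peak +- half-width, clipped to the waveform support.
#'
#' @param waveform numeric vector with a `times` attribute (seconds).
#' @param spec a [component_spec()].
#' @return list(peak_s, window = c(lo, hi)).
#' @export
find_component_window <- function(waveform, spec) {
  times <- attr(waveform, "times")
  if (is.null(times)) stop_fmt("waveform needs a 'times' attribute")
  if (!all(is.finite(waveform))) stop_fmt("waveform must be finite")
  sr <- spec$search_s
  if (sr[1] < times[1] - 1e-9 || sr[2] > times[length(times)] + 1e-9)
    stop_fmt("search window [%g, %g] outside waveform support", sr[1], sr[2])
  idx <- which(times >= sr[1] - 1e-9 & times <= sr[2] + 1e-9)
  v <- waveform[idx]
  if (spec$polarity == "negative") v <- -v
  pk <- idx[which.max(v)]                    # which.max: earliest tie wins
  if (pk == idx[1] || pk == idx[length(idx)])
    warning(sprintf("%s extremum at the edge of its search range (%g s)",
                    spec$name, times[pk]), call. = FALSE)
  w <- c(times[pk] - spec$half_width_s, times[pk] + spec$half_width_s)
  w <- c(max(w[1], times[1]), min(w[2], times[length(times)]))
  list(peak_s = times[pk], window = w)
}

#' Trial-level mean amplitudes over a component window
#'
#' For every retained trial and selected channel, averages the epoch over
#' the (closed) component window, yielding the long-format table that feeds
#' the trial-level mixed model.
#'
#' @param epochs an `epoch_set`.
#' @param window (lo, hi) window in seconds, inside the epoch.
#' @param channels channel labels.
#' @param participant participant id stamped on every row.
#' @return data.frame (participant, condition, channel, trial,
#'   amplitude_uv), one row per trial x channel.
#' @export
trial_window_means <- function(epochs, window, channels, participant = NA) {
  ic <- match(channels, epochs$labels)
  if (!length(ic) || anyNA(ic))
    stop_fmt("channel selection is empty or unknown")
  ti <- which(epochs$times >= window[1] - 1e-9 &
                epochs$times <= window[2] + 1e-9)
  if (!length(ti)) stop_fmt("window [%g, %g] contains no samples",
                            window[1], window[2])
  n_tr <- dim(epochs$data)[1]
  amp <- apply(epochs$data[, ic, ti, drop = FALSE], c(1, 2), mean)
  data.frame(
    participant = participant,
    condition = rep(epochs$trial_meta$condition, times = length(ic)),
    channel = rep(channels, each = n_tr),
    trial = rep(seq_len(n_tr), times = length(ic)),
    amplitude_uv = as.vector(amp),
    stringsAsFactors = FALSE
  )
}
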