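#' Amplitude envelope of the presented audio
#'
#' The modulus of the analytic (Hilbert-transformed) signal of the mono mix
#' (stereo is averaged first), low-pass filtered at `lp_edge_hz` with the
#' same Hamming FIR design as the EEG path, polyphase-resampled to
#' `target_srate_hz`, and clipped at zero (filter undershoot only).
#'
#' @param audio an `audio_track`, a samples x channels matrix, or a numeric
#'   vector; `srate_hz` is required unless `audio` carries it.
#' @param srate_hz input sampling rate (Hz).
#' @param target_srate_hz output rate (250 Hz to match the analysis grid).
#' @param lp_edge_hz low-pass passband edge (Hz).
#' @return list of class `envelope`: `values` (nonnegative) and `srate_hz`.
#' @export
extract_envelope <- function(audio, srate_hz = NULL, target_srate_hz = 250,
                             lp_edge_hz = 30) {
  if (inherits(audio, "audio_track") ||
      (is.list(audio) && !is.null(audio$waveform))) {
    srate_hz <- audio$srate_hz
    audio <- audio$waveform
  }
  if (is.matrix(audio)) audio <- rowMeans(audio)
  if (is.null(srate_hz)) stop_fmt("audio sampling rate unknown")
  if (!length(audio) || all(audio == 0)) {
    n_out <- ceiling(length(audio) * target_srate_hz / srate_hz)
    return(structure(list(values = numeric(n_out), srate_hz = target_srate_hz),
                     class = "envelope"))
  }
  env <- Mod(analytic_signal(audio))
  d <- design_fir(lp_edge_hz, "low", srate_hz)
  v <- apply_fir(matrix(env, nrow = 1), d$coef)
  v <- resample_rows(v, srate_hz, target_srate_hz)
  structure(list(values = pmax(as.numeric(v[1, ]), 0),
                 srate_hz = target_srate_hz),
            class = "envelope")
}

#' Excise target responses and return contiguous segments
#'
#' Removes the half-open interval `[onset, onset + exclusion_s)` around
#' every alarm and beep event (targets of either condition) from the paired
#' EEG/envelope series; overlapping exclusion zones are merged and the
#' remaining data are returned as maximal contiguous segments.
#'
#' @param eeg `eeg_recording` on the analysis grid.
#' @param env `envelope` (or numeric vector) on the same grid.
#' @param events (delay-corrected) event table.
#' @param exclusion_s excision length after each onset (s).
#' @return list of class `segment_set`: `segments` (each with `eeg`
#'   channels x n and `env` length n), `srate_hz`, `total_s`, `starts_s`.
#' @export
excise_targets <- function(eeg, env, events, exclusion_s = 1) {
  ev <- if (is.list(env) && !is.null(env$values)) env$values else env
  srate <- eeg$srate_hz
  n <- min(ncol(eeg$data), length(ev))
  dur <- n / srate
  tgt <- events[events$category %in% c("alarm", "beep"), , drop = FALSE]
  zones <- if (nrow(tgt))
    merge_intervals(pmax(0, tgt$onset_s),
                    pmin(dur, tgt$onset_s + exclusion_s))
  else matrix(numeric(0), ncol = 2)
  keep_s <- 0; segs <- list(); starts <- numeric(0)
  bounds <- rbind(c(NA, 0), zones, c(dur, NA))
  for (i in seq_len(nrow(bounds) - 1)) {
    a <- bounds[i, 2]; b <- bounds[i + 1, 1]
    if (b - a <= 0) next
    i0 <- sample_at(a, srate); i1 <- min(n, sample_at(b, srate) - 1L)
    if (i1 < i0) next
    segs[[length(segs) + 1]] <- list(eeg = eeg$data[, i0:i1, drop = FALSE],
                                     env = ev[i0:i1])
    starts <- c(starts, unname(a))
    keep_s <- keep_s + (i1 - i0 + 1) / srate
  }
  if (!length(segs)) stop_fmt("no data left after target excision")
  structure(list(segments = segs, srate_hz = srate, total_s = unname(keep_s),
                 starts_s = starts, labels = eeg$labels),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments, %.1f s total @ %g Hz\n",
              length(x$segments), x$total_s, x$srate_hz))
  invisible(x)
}

#' Equalize total segment length between conditions
#'
#' Drops whole segments, shortest first, from whichever condition is
#' currently longer until the total-length difference is below `tol_s`.
#' Dropped segment indices are recorded in the `dropped` attribute of each
#' returned set.
#'
#' @param segset_narrow,segset_wide `segment_set`s of the two conditions.
#' @param tol_s tolerance on the total-length difference (s; 60 by default).
#' @return list(narrow, wide) of trimmed `segment_set`s.
#' @export
equalize_lengths <- function(segset_narrow, segset_wide, tol_s = 60) {
  sets <- list(narrow = segset_narrow, wide = segset_wide)
  dropped <- list(narrow = integer(0), wide = integer(0))
  orig <- list(narrow = seq_along(segset_narrow$segments),
               wide = seq_along(segset_wide$segments))
  seg_len <- function(s) vapply(s$segments, function(g) length(g$env), numeric(1)) /
    s$srate_hz
  totals <- vapply(sets, function(s) s$total_s, numeric(1))
  while (abs(totals[1] - totals[2]) >= tol_s) {
    longer <- names(which.max(totals))
    lens <- seg_len(sets[[longer]])
    if (length(lens) <= 1)
      stop_fmt("cannot equalize lengths without emptying the %s condition", longer)
    k <- which.min(lens)
    dropped[[longer]] <- c(dropped[[longer]], orig[[longer]][k])
    orig[[longer]] <- orig[[longer]][-k]
    sets[[longer]]$segments <- sets[[longer]]$segments[-k]
    sets[[longer]]$starts_s <- sets[[longer]]$starts_s[-k]
    sets[[longer]]$total_s <- sets[[longer]]$total_s - lens[k]
    totals[longer] <- sets[[longer]]$total_s
  }
  attr(sets$narrow, "dropped") <- dropped$narrow
  attr(sets$wide, "dropped") <- dropped$wide
  sets
}

#' Multiply the EEG blocks of a segment set by a scale factor
#'
#' @param segset a `segment_set`.
#' @param factor positive scale (0.0313 in the standard configuration).
#' @return the scaled set; the factor is recorded in `scale_applied`.
#' @export
scale_eeg <- function(segset, factor) {
  if (!is.finite(factor) || factor <= 0) stop_fmt("scale factor must be positive")
  segset$segments <- lapply(segset$segments, function(g) {
    g$eeg <- g$eeg * factor
    g
  })
  segset$scale_applied <- (segset$scale_applied %||% 1) * factor
  segset
}

# Lagged design matrix for one segment: column j holds env shifted by
# lags[j] samples, zero-padded at the segment edges.
lagged_design <- function(env, lags) {
  n <- length(env)
  max_l <- max(lags, 0); min_l <- min(lags, 0)
  ep <- c(numeric(max_l), env, numeric(-min_l))
  idx <- outer(seq_len(n), lags, function(t, l) t - l + max_l)
  matrix(ep[idx], nrow = n)
}

#' Fit the forward (encoding) TRF by ridge regression
#'
#' Per channel, solves `(X'X + lambda I) w = X'y`, where X stacks lagged
#' copies of the envelope (one column per lag, zero-padded at segment edges)
#' plus an unpenalized intercept, with covariance accumulated across the
#' unequal segments -- segments are never concatenated across excision gaps.
#'
#' @param segset a `segment_set` (scaled EEG + envelope).
#' @param lags_s (min, max) lag range in seconds; the lag axis is
#'   `round(min*srate) .. round(max*srate)` inclusive (251 points for
#'   -0.2..0.8 s at 250 Hz).
#' @param lambda ridge penalty on the lag coefficients (intercept free).
#' @return `trf_model`: `weights` (lags x channels, microvolts per unit
#'   envelope per sample), `bias`, `lags_s`, `lambda`, `scale_applied`.
#' @export
fit_forward_trf <- function(segset, lags_s = c(-0.2, 0.8), lambda = 0.1) {
  srate <- segset$srate_hz
  lags <- seq.int(round(lags_s[1] * srate), round(lags_s[2] * srate))
  nl <- length(lags)
  nch <- nrow(segset$segments[[1]]$eeg)
  XtX <- matrix(0, nl + 1, nl + 1)
  Xty <- matrix(0, nl + 1, nch)
  used <- 0L; skipped <- 0L
  for (g in segset$segments) {
    n <- length(g$env)
    if (n < nl) { skipped <- skipped + 1L; next }
    acc <- trf_accumulate_cpp(g$env, g$eeg, as.integer(lags))
    XtX <- XtX + acc$XtX
    Xty <- Xty + acc$Xty
    used <- used + n
  }
  if (skipped)
    warning(sprintf("%d segment(s) shorter than the lag span were skipped",
                    skipped), call. = FALSE)
  if (used == 0) stop_fmt("no segment long enough for the lag span")
  pen <- diag(c(rep(lambda, nl), 0))
  W <- tryCatch(solve(XtX + pen, Xty), error = function(e)
    stop_fmt("normal equations singular%s: %s",
             if (lambda == 0) " at lambda = 0; use lambda > 0" else "",
             conditionMessage(e)))
  structure(list(weights = W[seq_len(nl), , drop = FALSE],
                 bias = W[nl + 1, ],
                 lags_s = lags / srate, lambda = lambda,
                 scale_applied = segset$scale_applied %||% 1,
                 srate_hz = srate, labels = segset$labels,
                 n_samples = used),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d lags [%g, %g] s x %d channels, lambda %g, fit on %d samples\n",
              length(x$lags_s), min(x$lags_s), max(x$lags_s),
              ncol(x$weights), x$lambda, x$n_samples))
  invisible(x)
}

#' Baseline-correct TRF weights
#'
#' Subtracts, per channel, the mean weight over the baseline lag window
#' (closed interval) from all lags. Idempotent.
#'
#' @param trf a `trf_model`.
#' @param window_s baseline lag window (s), inside the lag range.
#' @return the corrected model.
#' @export
baseline_trf <- function(trf, window_s = c(-0.1, 0)) {
  idx <- which(trf$lags_s >= window_s[1] - 1e-9 &
                 trf$lags_s <= window_s[2] + 1e-9)
  if (!length(idx)) stop_fmt("baseline window outside the lag range")
  trf$weights <- sweep(trf$weights, 2, colMeans(trf$weights[idx, , drop = FALSE]))
  trf
}

#' Global field power of a TRF
#'
#' Per lag, the population standard deviation (divide by N) across
#' channels; invariant to channel permutation and blind to offsets common
#' to all channels.
#'
#' @param trf a `trf_model` (or a lags x channels matrix with >= 2 columns).
#' @return numeric GFP series with a `lags_s` attribute when available.
#' @export
gfp <- function(trf) {
  W <- if (inherits(trf, "trf_model")) trf$weights else as.matrix(trf)
  if (ncol(W) < 2) stop_fmt("GFP needs at least 2 channels")
  v <- sqrt(rowMeans((W - rowMeans(W))^2))
  if (inherits(trf, "trf_model")) attr(v, "lags_s") <- trf$lags_s
  v
}

#' Individual GFP peak and FWHM window inside a significant window
#'
#' Averages the two condition GFPs, finds the maximum within the
#' significant lag window (earliest tie wins), and expands the maximal
#' contiguous run of lags around the peak where the averaged GFP stays at
#' or above half the peak value, clipped to the significant window. A
#' non-positive peak degenerates to the single peak sample.
#'
#' @param gfp_narrow,gfp_wide GFP series with `lags_s` attributes (or
#'   plain vectors sharing `lags_s`).
#' @param sig_window (t0, t1) significant lag window (s).
#' @param lags_s lag axis, taken from `gfp_narrow` when absent.
#' @return list(peak_s, window = c(lo, hi), degenerate).
#' @export
individual_fwhm_window <- function(gfp_narrow, gfp_wide, sig_window,
                                   lags_s = NULL) {
  lags_s <- lags_s %||% attr(gfp_narrow, "lags_s")
  if (is.null(lags_s)) stop_fmt("lag axis unknown")
  avg <- (as.numeric(gfp_narrow) + as.numeric(gfp_wide)) / 2
  idx <- which(lags_s >= sig_window[1] - 1e-9 & lags_s <= sig_window[2] + 1e-9)
  if (!length(idx)) stop_fmt("significant window outside the lag range")
  pk_rel <- which.max(avg[idx])
  pk <- idx[pk_rel]
  peak_val <- avg[pk]
  if (peak_val <= 0)
    return(list(peak_s = lags_s[pk], window = rep(lags_s[pk], 2),
                degenerate = TRUE))
  half <- peak_val / 2
  lo <- pk
  while (lo > idx[1] && avg[lo - 1] >= half) lo <- lo - 1
  hi <- pk
  while (hi < idx[length(idx)] && avg[hi + 1] >= half) hi <- hi + 1
  list(peak_s = lags_s[pk], window = c(lags_s[lo], lags_s[hi]),
       degenerate = FALSE)
}

#' Average each condition's GFP over a shared window
#'
#' @param gfp_by_condition named list (narrow, wide) of GFP series.
#' @param window (lo, hi) lag window in seconds (individual FWHM window or a
#'   fixed group window).
#' @param lags_s lag axis, taken from the first series when absent.
#' @return named numeric vector of per-condition means.
#' @export
window_gfp_means <- function(gfp_by_condition, window, lags_s = NULL) {
  lags_s <- lags_s %||% attr(gfp_by_condition[[1]], "lags_s")
  idx <- which(lags_s >= window[1] - 1e-9 & lags_s <= window[2] + 1e-9)
  if (!length(idx)) stop_fmt("window contains no lags")
  vapply(gfp_by_condition, function(g) mean(as.numeric(g)[idx]), numeric(1))
}
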