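#' Flag flat or abnormally noisy channels
#'
#' A channel is flagged when its total range is below `flat_tol_uv` (a flat
#' line) or when the robust z-score of its log-variance (median/MAD across
#' channels) exceeds `var_z_thresh`. In a two-condition design the flags of
#' both runs should be unioned so bad channels are removed from both
#' conditions jointly.
#'
#' @param rec an `eeg_recording` (at least 4 channels).
#' @param flat_tol_uv flat-line range tolerance (microvolts).
#' @param var_z_thresh robust z threshold on log-variance.
#' @return character vector of flagged labels.
#' @export
flag_bad_channels <- function(rec, flat_tol_uv = 0.5, var_z_thresh = 4) {
  if (nrow(rec$data) < 4) stop_fmt("need at least 4 channels")
  rng <- apply(rec$data, 1, function(x) diff(range(x)))
  flat <- rng < flat_tol_uv
  # robust spread (MAD^2) so that sparse transients such as blinks do not
  # masquerade as broken channels
  lv <- log(pmax(apply(rec$data, 1, stats::mad)^2, 1e-30))
  # scale floor of 0.2 log-units: in a near-homogeneous montage the spread
  # estimate collapses and sampling noise alone would trip the threshold
  z <- (lv - stats::median(lv)) / max(stats::mad(lv), 0.2)
  noisy <- abs(z) > var_z_thresh & !flat
  flags <- rec$labels[flat | noisy]
  if (length(flags) > length(rec$labels) / 2)
    stop_fmt("more than half of the channels (%d/%d) look bad",
             length(flags), length(rec$labels))
  flags
}

# Perrin-style spherical-spline basis g(cos angle): order-m splines,
# truncated Legendre series.
spline_g <- function(cosang, m = 4, n_terms = 50) {
  cosang <- as.matrix(cosang)
  cosang[] <- pmin(1, pmax(-1, cosang))
  # Legendre recurrence evaluated for all entries at once
  p_prev <- matrix(1, nrow(cosang), ncol(cosang))
  p_cur <- cosang
  g <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    g <- g + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur; p_cur <- p_new
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel by an order-4 spherical-spline interpolation
#' (truncated Legendre expansion, small diagonal regularization) of the good
#' channels; good channels are untouched. Reproduces constant fields
#' exactly.
#'
#' @param rec an `eeg_recording` with unit-sphere positions.
#' @param bads labels to interpolate (subset of the montage).
#' @param reg diagonal regularization of the spline system.
#' @return recording with bad channels replaced; the interpolated set is
#'   recorded in the `interpolated` field and `bads` is cleared.
#' @export
interpolate_spherical <- function(rec, bads, reg = 1e-5) {
  if (!length(bads)) return(rec)
  if (is.null(rec$positions))
    stop_fmt("channel positions are required for spherical interpolation")
  if (!all(bads %in% rec$labels))
    stop_fmt("unknown channels: %s", paste(setdiff(bads, rec$labels), collapse = ", "))
  good <- setdiff(rec$labels, bads)
  if (length(good) < 4) stop_fmt("need at least 4 good channels")
  ig <- match(good, rec$labels); ib <- match(bads, rec$labels)
  pg <- rec$positions[ig, , drop = FALSE]
  pb <- rec$positions[ib, , drop = FALSE]
  G <- spline_g(pg %*% t(pg))
  Gb <- spline_g(pb %*% t(pg))
  k <- length(good)
  A <- rbind(cbind(G + diag(reg, k), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(rec$data[ig, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(k), , drop = FALSE]; cc <- sol[k + 1, ]
  rec$data[ib, ] <- Gb %*% w + matrix(cc, length(ib), ncol(rec$data), byrow = TRUE)
  rec$interpolated <- union(rec$interpolated, bads)
  rec$bads <- setdiff(rec$bads, bads)
  rec
}

#' Re-reference to the linked mastoids
#'
#' Subtracts the mean of TP9 and TP10 from every channel and records the new
#' reference. Between-channel differences are unchanged; after application
#' the mastoid mean is identically zero.
#'
#' @param rec an `eeg_recording` containing TP9 and TP10.
#' @return the re-referenced recording.
#' @export
rereference_linked_mastoids <- function(rec) {
  im <- match(c("TP9", "TP10"), rec$labels)
  if (anyNA(im))
    stop_fmt("mastoid channel %s missing",
             paste(c("TP9", "TP10")[is.na(im)], collapse = ", "))
  ref <- colMeans(rec$data[im, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref)
  rec$reference <- "linked-mastoid"
  rec
}

#' Shift event onsets by the constant sound-marker delay
#'
#' @param events event table.
#' @param delay_s constant delay (s), added to every onset (19 ms default
#'   latency between marker and sound presentation).
#' @return the shifted table.
#' @export
correct_marker_delay <- function(events, delay_s = 0.019) {
  if (!is.finite(delay_s)) stop_fmt("delay must be finite")
  events$onset_s <- events$onset_s + delay_s
  # key presses are captured in real time and carry no marker delay
  events
}

#' Threshold-based epoch rejection
#'
#' For each epoch and channel the within-epoch amplitude SD is computed;
#' the "local" statistic standardizes it across epochs per channel and the
#' "global" statistic standardizes the channel-mean SD across epochs. An
#' epoch is flagged when any |local z| or the |global z| exceeds
#' `sd_thresh`. Data are untouched; only a mask is returned. Zero-variance
#' statistics yield z = 0, so identical epochs are never rejected, and the
#' mask is invariant to rescaling all data by a positive constant.
#'
#' @param epochs an `epoch_set` or a trials x channels x samples array
#'   (at least 3 epochs).
#' @param sd_thresh threshold in standard deviations (2 for continuous
#'   cleaning, 3 for ERP epochs).
#' @return data.frame (epoch_index, global_z, rejected, reason) with the
#'   per-channel local z matrix in attribute `"channel_z"`.
#' @export
reject_epochs <- function(epochs, sd_thresh) {
  x <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  if (length(dim(x)) != 3) stop_fmt("epochs must be a 3-d array")
  n_ep <- dim(x)[1]
  if (n_ep < 3) stop_fmt("need at least 3 epochs")
  s <- apply(x, c(1, 2), stats::sd)              # epoch x channel SD
  zcol <- function(v) {
    sdv <- stats::sd(v)
    if (!is.finite(sdv) || sdv == 0) return(rep(0, length(v)))
    (v - mean(v)) / sdv
  }
  local_z <- apply(s, 2, zcol)
  if (is.null(dim(local_z))) local_z <- matrix(local_z, nrow = n_ep)
  global_z <- zcol(rowMeans(s))
  loc_hit <- apply(abs(local_z) > sd_thresh, 1, any)
  glob_hit <- abs(global_z) > sd_thresh
  mask <- data.frame(
    epoch_index = seq_len(n_ep),
    global_z = global_z,
    rejected = loc_hit | glob_hit,
    reason = ifelse(glob_hit, "global", ifelse(loc_hit, "local", "none")),
    stringsAsFactors = FALSE
  )
  if (all(mask$rejected)) stop_fmt("all %d epochs rejected", n_ep)
  attr(mask, "channel_z") <- local_z
  mask
}

#' Remove stereotyped ocular (blink) artifacts
#'
#' Deterministic fallback for component-based artifact removal: blinks are
#' detected on the smoothed mean of the most frontal channels (robust z > 6
#' sustained for at least 20 ms), a blink regressor is built by placing a
#' template at each detected peak, and the regressor is projected out of
#' every channel. With no detections the data pass through unchanged. An
#' external decomposition can be substituted via `hook`, a function
#' `recording -> recording` honoring the same contract.
#'
#' @param rec an `eeg_recording` with positions (to find frontal channels).
#' @param blink_template optional template waveform at the recording rate;
#'   default a 350 ms squared-sine bump.
#' @param hook optional replacement artifact-removal function.
#' @return the cleaned recording.
#' @export
remove_ocular <- function(rec, blink_template = NULL, hook = NULL) {
  if (!is.null(hook)) return(hook(rec))
  srate <- rec$srate_hz
  fr <- intersect(c("Fp1", "Fp2"), rec$labels)
  if (!length(fr)) {
    if (is.null(rec$positions)) stop_fmt("no frontal channels identifiable")
    fr <- rec$labels[order(-rec$positions[, 2])[1:2]]
  }
  f <- colMeans(rec$data[match(fr, rec$labels), , drop = FALSE])
  # smooth with a 50 ms moving average
  k <- max(3L, round(0.05 * srate)); k <- k + (1 - k %% 2)
  fs <- stats::filter(f, rep(1 / k, k), sides = 2)
  fs[is.na(fs)] <- 0
  z <- (fs - stats::median(fs)) / max(stats::mad(fs), 1e-12)
  scale_z <- max(stats::mad(fs), 1e-12)
  med <- stats::median(fs)
  if (!any(z > 6)) return(rec)
  tmpl <- blink_template %||%
    sin(pi * seq(0, 1, by = 1 / (0.35 * srate)))^2
  half <- floor(length(tmpl) / 2)
  k_sm <- rep(1 / k, k)
  tmpl_sm <- as.numeric(stats::filter(c(numeric(k), tmpl, numeric(k)),
                                      k_sm, sides = 2))[k + seq_along(tmpl)]
  tmpl_sm[is.na(tmpl_sm)] <- 0
  place <- function(vec, pk, shape, w) {
    idx <- (pk - half):(pk - half + length(shape) - 1L)
    keep <- idx >= 1 & idx <= length(vec)
    vec[idx[keep]] <- vec[idx[keep]] + w * shape[keep]
    vec
  }
  # matching pursuit on the smoothed frontal trace, so that overlapping
  # blinks (closer than a template width) are each assigned a template
  resid <- as.numeric(fs)
  peaks <- integer(0)
  while (length(peaks) < 500) {
    pk <- which.max(resid)
    if ((resid[pk] - med) / scale_z <= 6) break
    peaks <- c(peaks, pk)
    resid <- place(resid, pk, tmpl_sm, -(resid[pk] - med))
  }
  if (!length(peaks)) return(rec)
  # joint least squares with one template column per blink, per channel
  R <- sapply(peaks, function(pk)
    place(numeric(ncol(rec$data)), pk, tmpl, 1))
  B <- solve(crossprod(R) + diag(1e-8, ncol(R)), crossprod(R, t(rec$data)))
  rec$data <- rec$data - t(R %*% B)
  attr(rec, "n_blinks_removed") <- length(peaks)
  rec
}

#' Condition a continuous recording (fixed stage order)
#'
#' Applies, in this order: Hamming FIR band filtering, polyphase resampling,
#' spherical interpolation of the given bad channels, ocular-artifact
#' removal, and linked-mastoid re-referencing. The order and every decision
#' are recorded in the returned recording's `log` attribute.
#'
#' @param rec raw `eeg_recording`.
#' @param config a [pipeline_config()].
#' @param bads bad channels (flag on both conditions and pass the union).
#' @param ocular_hook optional replacement for the blink-removal stage.
#' @return preprocessed recording at `config$target_srate_hz`.
#' @export
preprocess_recording <- function(rec, config = pipeline_config(),
                                 bads = character(0), ocular_hook = NULL) {
  # filter -> resample, fused into one convolution pass: the band kernel and
  # the resampler's anti-alias kernel are combined before the (single)
  # zero-phase application, then the decimation grid is taken -- identical
  # (up to rounding) to applying fir_filter() and resample_recording() in
  # sequence, at half the transform cost.
  q <- rec$srate_hz / config$target_srate_hz
  dhp <- design_fir(config$hp_edge_hz, "high", rec$srate_hz)
  dlp <- design_fir(config$lp_edge_hz, "low", rec$srate_hz)
  spec <- list(high = dhp[c("order", "cutoff_hz", "tbw_hz")],
               low = dlp[c("order", "cutoff_hz", "tbw_hz")])
  b <- stats::convolve(dhp$coef, rev(dlp$coef), type = "open")
  if (abs(q - round(q)) < 1e-9 && round(q) > 1) {
    q <- round(q)
    ord <- max(64L, 16L * q); ord <- ord + ord %% 2L
    baa <- as.numeric(signal::fir1(ord, 0.9 / q, type = "low"))
    b <- stats::convolve(b, rev(baa), type = "open")
    rec$data <- apply_fir(rec$data, b)[, seq(1, ncol(rec$data), by = q),
                                       drop = FALSE]
    rec$srate_hz <- config$target_srate_hz
  } else {
    rec$data <- apply_fir(rec$data, b)
    rec <- resample_recording(rec, config$target_srate_hz)
  }
  rec <- interpolate_spherical(rec, bads)
  rec <- remove_ocular(rec, hook = ocular_hook)
  n_blinks <- attr(rec, "n_blinks_removed") %||% 0L
  rec <- rereference_linked_mastoids(rec)
  attr(rec, "log") <- list(
    order = c("filter", "resample", "interpolate", "ocular", "rereference"),
    filter_spec = spec, interpolated = bads, n_blinks_removed = n_blinks
  )
  rec
}
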