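#' Hamming-window FIR design for the standard filter heuristic
#'
#' Transition bandwidth is `max(0.25 * edge, min(2 Hz, edge))`; the -6 dB
#' cutoff is shifted from the passband edge by half the transition band
#' toward the stopband (below the edge for a high-pass, above it for a
#' low-pass), so the passband edge itself keeps ~unity gain. The order is
#' `ceiling(3.3 / normalized transition bandwidth)`, rounded up to even.
#'
#' @param edge_hz passband edge (Hz).
#' @param type `"high"` or `"low"`.
#' @param srate_hz sampling rate.
#' @return list(coef, order, cutoff_hz, tbw_hz).
#' @export
design_fir <- function(edge_hz, type = c("high", "low"), srate_hz) {
  type <- match.arg(type)
  if (!is.finite(edge_hz) || edge_hz <= 0 || edge_hz >= srate_hz / 2)
    stop_fmt("filter edge %.3g Hz must lie in (0, Nyquist = %g Hz)",
             edge_hz, srate_hz / 2)
  tbw <- max(0.25 * edge_hz, min(2, edge_hz))
  cutoff <- if (type == "high") edge_hz - tbw / 2 else edge_hz + tbw / 2
  n <- ceiling(3.3 / (tbw / srate_hz))
  n <- n + n %% 2          # even order -> odd-length, type-I linear phase
  if (type == "low") {
    b <- as.numeric(signal::fir1(n, cutoff / (srate_hz / 2), type = "low"))
  } else {
    # spectral inversion of the complementary low-pass puts an exact null
    # at DC (the low-pass is renormalized to unit DC gain first)
    blp <- as.numeric(signal::fir1(n, cutoff / (srate_hz / 2), type = "low"))
    b <- -blp / sum(blp)
    b[n / 2 + 1] <- b[n / 2 + 1] + 1
  }
  list(coef = b, order = n, cutoff_hz = cutoff, tbw_hz = tbw)
}

# Zero-phase application of linear-phase FIR coefficients to a matrix of
# channels (rows): reflect-pad both ends by the group delay, filter once by
# FFT convolution, and shift back by the group delay.
apply_fir <- function(data, b) {
  gd <- (length(b) - 1) / 2
  n <- ncol(data)
  pad_l <- min(gd, n - 1); pad_r <- min(gd, n - 1)
  padded <- cbind(2 * data[, 1] - data[, (pad_l + 1):2, drop = FALSE],
                  data,
                  2 * data[, n] - data[, (n - 1):(n - pad_r), drop = FALSE])
  y <- fft_filter_rows(padded, b)
  y[, (gd + pad_l + 1):(gd + pad_l + n), drop = FALSE]
}

#' FIR-filter a recording (zero-phase)
#'
#' High-pass and/or low-pass Hamming-window FIR filtering with group-delay
#' compensation and edge padding, so the output has the same length as the
#' input. When both edges are given the two kernels are combined into a
#' single band-pass kernel and applied in one pass (identical to sequential
#' application).
#'
#' @param rec an `eeg_recording`.
#' @param hp_edge_hz,lp_edge_hz passband edges (Hz); either may be NULL.
#' @return the filtered recording.
#' @export
fir_filter <- function(rec, hp_edge_hz = NULL, lp_edge_hz = NULL) {
  if (is.null(hp_edge_hz) && is.null(lp_edge_hz))
    stop_fmt("at least one filter edge must be given")
  b <- 1
  specs <- list()
  if (!is.null(hp_edge_hz)) {
    d <- design_fir(hp_edge_hz, "high", rec$srate_hz)
    b <- if (identical(b, 1)) d$coef else stats::convolve(b, rev(d$coef), type = "open")
    specs$high <- d[c("order", "cutoff_hz", "tbw_hz")]
  }
  if (!is.null(lp_edge_hz)) {
    d <- design_fir(lp_edge_hz, "low", rec$srate_hz)
    b <- if (identical(b, 1)) d$coef else stats::convolve(b, rev(d$coef), type = "open")
    specs$low <- d[c("order", "cutoff_hz", "tbw_hz")]
  }
  rec$data <- apply_fir(rec$data, b)
  attr(rec, "filter_spec") <- specs
  rec
}

#' Resample a recording (polyphase, anti-aliased)
#'
#' Rational-factor polyphase resampling of every channel. Only downsampling
#' (or the identity) is supported; event times in seconds remain valid.
#'
#' @param rec an `eeg_recording`.
#' @param target_srate_hz new sampling rate (Hz), at most the native rate.
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_srate_hz) {
  if (target_srate_hz > rec$srate_hz)
    stop_fmt("upsampling (%g -> %g Hz) is not supported",
             rec$srate_hz, target_srate_hz)
  if (abs(target_srate_hz - rec$srate_hz) < 1e-9) return(rec)
  rec$data <- resample_rows(rec$data, rec$srate_hz, target_srate_hz)
  rec$srate_hz <- target_srate_hz
  rec
}

# Polyphase row-wise resampling. Integer decimation factors take the fast
# path (one anti-alias Hamming FIR at 0.9 x the new Nyquist, zero-phase,
# then index); other rational ratios fall back to signal::resample.
resample_rows <- function(data, srate_from, srate_to) {
  ratio <- srate_from / srate_to
  q <- round(ratio)
  if (abs(ratio - q) < 1e-9 && q >= 1) {
    if (q == 1) return(data)
    ord <- max(64L, 16L * q)
    ord <- ord + ord %% 2L
    b <- as.numeric(signal::fir1(ord, 0.9 / q, type = "low"))
    y <- apply_fir(data, b)
    y[, seq(1, ncol(data), by = q), drop = FALSE]
  } else {
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    fr <- round(srate_to * 1e6); fn <- round(srate_from * 1e6)
    gg <- g(fr, fn)
    t(apply(data, 1, function(x) signal::resample(x, fr / gg, fn / gg)))
  }
}
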