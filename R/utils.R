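#' @importFrom stats fft rnorm runif sd quantile median mad approx setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real series, i.e. the series whose
#' real part is the input and whose modulus is the instantaneous amplitude
#' envelope. Constructed by zeroing negative frequencies and doubling positive
#' ones in the DFT.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  nfft <- stats::nextn(n, c(2, 3, 5))     # zero-pad to a fast length
  if (nfft %% 2) nfft <- stats::nextn(nfft + 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  h <- numeric(nfft)
  h[1] <- 1; h[nfft / 2 + 1] <- 1
  h[2:(nfft / 2)] <- 2
  (stats::fft(X * h, inverse = TRUE) / nfft)[seq_len(n)]
}

# FFT-based linear convolution of a (long) signal with FIR coefficients b;
# returns the full convolution head of length nx + nb - 1.
fft_filter <- function(x, b) {
  nx <- length(x); nb <- length(b)
  nfft <- stats::nextn(nx + nb - 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - nx)))
  B <- stats::fft(c(b, numeric(nfft - nb)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / nfft
  y[seq_len(nx + nb - 1)]
}

# Multi-channel FFT convolution (rows = channels). Channels are packed in
# pairs into complex signals (convolution with a real kernel is linear, so
# the real and imaginary parts stay separated) and transformed together
# with mvfft, halving the number of transforms and keeping the loop in C.
fft_filter_rows <- function(data, b) {
  nch <- nrow(data); nx <- ncol(data); nb <- length(b)
  ny <- nx + nb - 1
  nfft <- stats::nextn(ny, c(2, 3, 5))
  B <- stats::fft(c(b, numeric(nfft - nb)))
  odd <- seq(1L, nch, by = 2L)
  even <- pmin(odd + 1L, nch)            # last pair may duplicate a row
  Z <- matrix(0i, nfft, length(odd))
  Z[seq_len(nx), ] <- complex(real = t(data[odd, , drop = FALSE]),
                              imaginary = t(data[even, , drop = FALSE]))
  W <- stats::mvfft(stats::mvfft(Z) * B, inverse = TRUE) / nfft
  W <- W[seq_len(ny), , drop = FALSE]
  out <- matrix(0, nch, ny)
  out[odd, ] <- t(Re(W))
  out[setdiff(even, odd), ] <- t(Im(W[, even > odd, drop = FALSE]))
  out
}

# Merge possibly-overlapping half-open intervals [a, b); returns a matrix with
# columns (start, end), sorted, disjoint.
merge_intervals <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) return(matrix(numeric(0), ncol = 2))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1]; out_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    k <- length(out_s)
    if (starts[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, ends[i])
    }
  }
  cbind(start = out_s, end = out_e)
}

# Inverse-Gaussian deviates (Michael, Schucany & Haas 1976).
rinvgauss <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  z <- stats::runif(n)
  ifelse(z <= mu / (mu + x), x, mu^2 / x)
}

# 1/f ("pink-ish") Gaussian noise with spectral exponent alpha, flattened
# below 1 Hz so the very lowest bins do not dominate, plus a small white
# floor. Scaled to the requested standard deviation.
one_over_f_noise <- function(n, srate, alpha = 1, sd_target = 1) {
  as.numeric(one_over_f_noise_rows(n, 1, srate, alpha, sd_target))
}

# Matrix of independent 1/f noise channels (rows), synthesized in the
# frequency domain: a complex spectrum with iid Gaussian real/imaginary
# parts shaped by a real gain inverts to a complex series whose real and
# imaginary parts are two independent real noise channels with that
# spectrum, so each transform yields two channels (compiled kernel).
one_over_f_noise_rows <- function(n, nch, srate, alpha = 1, sd_target = 1) {
  if (n < 4L) return(matrix(stats::rnorm(n * nch, sd = sd_target), nch, n))
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- seq(0, srate, length.out = nfft + 1)[seq_len(nfft)]
  f[f > srate / 2] <- srate - f[f > srate / 2]   # mirror to physical frequency
  gain <- pmax(f, 1)^(-alpha / 2)
  gain[1] <- 0                                    # no DC
  rms <- sqrt(mean(gain^2))
  gain <- sqrt(gain^2 + (0.2 * rms)^2)            # white floor folded in
  gain <- gain / sqrt(mean(gain^2))               # unit-variance output
  npair <- ceiling(nch / 2)
  spec <- matrix(complex(real = stats::rnorm(nfft * npair),
                         imaginary = stats::rnorm(nfft * npair)) * gain,
                 nfft, npair)
  Z <- stats::mvfft(spec, inverse = TRUE) / sqrt(nfft)
  Z <- Z[seq_len(n), , drop = FALSE]
  out <- matrix(0, nch, n)
  odd <- seq(1L, nch, by = 2L)
  out[odd, ] <- t(Re(Z))
  even <- odd + 1L
  keep <- even <= nch
  out[even[keep], ] <- t(Im(Z[, keep, drop = FALSE]))
  out * sd_target
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# Seconds -> 1-based sample index of the sample containing time t
# (samples live at times (i-1)/srate; onset sample = floor(t*srate)).
sample_at <- function(t_s, srate) floor(t_s * srate) + 1L
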