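#' Max-t sign-flip permutation windows for TRF weights
#'
#' Tests, condition-independently, where the group TRF differs from zero:
#' a one-sample t statistic against zero at every (lag, channel) cell in the
#' test range, family-wise corrected by the permutation distribution of the
#' maximum |t| under random participant sign flips. A lag is significant
#' when any channel's corrected p-value is at most `alpha`; contiguous
#' significant lags merge into windows.
#'
#' Because flipping a participant's sign leaves its squared values
#' unchanged, only the permuted means need recomputing, which keeps the
#' permutation loop a single matrix product.
#'
#' @param trfs participant TRFs: a list of `trf_model`s (already averaged
#'   over conditions and baseline corrected) or a participants x lags x
#'   channels array.
#' @param lags_s lag axis (taken from the first model if available).
#' @param test_range_s lag range to test (s).
#' @param alpha family-wise significance level.
#' @param n_perm number of sign-flip permutations (a warning is issued
#'   below 100).
#' @param seed integer seed for the permutation draws.
#' @return list: `windows` (data.frame t0_s, t1_s), `tmax_threshold` (the
#'   (1-alpha) quantile of the permutation max distribution), `sig_lags`,
#'   `p` (lags x channels corrected p-values), `t_obs`, `lags_s`.
#' @export
tmax_windows <- function(trfs, lags_s = NULL, test_range_s = c(0, 0.45),
                         alpha = 0.05, n_perm = 2000, seed = NULL) {
  if (is.list(trfs) && inherits(trfs[[1]], "trf_model")) {
    lags_s <- lags_s %||% trfs[[1]]$lags_s
    arr <- aperm(simplify2array(lapply(trfs, function(m) m$weights)), c(3, 1, 2))
  } else {
    arr <- trfs
    if (is.null(lags_s)) stop_fmt("lag axis required for array input")
  }
  n_p <- dim(arr)[1]
  if (n_p < 5) stop_fmt("need at least 5 participants (got %d)", n_p)
  if (n_perm < 100)
    warning("fewer than 100 permutations gives a coarse null", call. = FALSE)
  li <- which(lags_s >= test_range_s[1] - 1e-9 &
                lags_s <= test_range_s[2] + 1e-9)
  nl <- length(li); nch <- dim(arr)[3]
  X <- matrix(arr[, li, , drop = FALSE], nrow = n_p)   # n_p x (nl*nch)
  ss <- colSums(X^2)
  tstat <- function(m) {
    v <- (ss / n_p - m^2) * n_p / (n_p - 1)
    out <- m / sqrt(v / n_p)
    out[!is.finite(out)] <- 0                          # zero-variance cells
    out
  }
  t_obs <- tstat(colMeans(X))
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n_p, replace = TRUE), n_perm, n_p)
    MP <- (S %*% X) / n_p
    VP <- sweep(-MP^2, 2, ss / n_p, `+`) * n_p / (n_p - 1)
    TP <- MP / sqrt(VP / n_p)
    TP[!is.finite(TP)] <- 0
    TP <- abs(TP)
    max_t <- TP[cbind(seq_len(n_perm),
                      max.col(TP, ties.method = "first"))]
    sorted <- sort(max_t)
    # #{max_t >= t0} without a pass per cell
    counts <- n_perm - findInterval(abs(t_obs), sorted, left.open = TRUE)
    p <- matrix((1 + counts) / (n_perm + 1), nl, nch)
    thr <- sort(max_t)[ceiling((1 - alpha) * (n_perm + 1))]
    if (is.na(thr)) thr <- max(max_t)
    sig <- apply(p <= alpha, 1, any)
    windows <- if (any(sig)) {
      r <- rle(sig)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      keep <- which(r$values)
      data.frame(t0_s = lags_s[li][starts[keep]],
                 t1_s = lags_s[li][ends[keep]])
    } else data.frame(t0_s = numeric(0), t1_s = numeric(0))
    list(windows = windows, tmax_threshold = thr, sig_lags = sig,
         p = p, t_obs = matrix(t_obs, nl, nch), lags_s = lags_s[li],
         n_perm = n_perm, alpha = alpha)
  })
}
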