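test_that("envelope extraction recovers amplitude, silence, and modulators", {
  srate <- 1000
  t <- seq(0, 10 - 1 / srate, by = 1 / srate)
  # pure 100 Hz sine of amplitude a -> envelope ~ a on interior samples
  a <- 0.8
  env <- extract_envelope(a * sin(2 * pi * 100 * t), srate, 250)
  interior <- seq(500, 2000)
  expect_equal(mean(env$values[interior]), a, tolerance = 0.01)
  expect_equal(env$srate_hz, 250)
  # silence -> zeros
  z <- extract_envelope(numeric(4000), srate, 250)
  expect_true(all(z$values == 0))
  # 2 Hz modulated 100 Hz carrier: envelope tracks the modulator
  mod <- 0.5 * (1 + 0.9 * sin(2 * pi * 2 * t))
  env2 <- extract_envelope(mod * sin(2 * pi * 100 * t), srate, 250)
  mod250 <- mod[seq(1, length(mod), by = 4)]
  expect_gt(cor(env2$values[interior], mod250[interior]), 0.99)
  # stereo input averaged to mono first
  st <- cbind(mod * sin(2 * pi * 100 * t), mod * sin(2 * pi * 100 * t))
  env3 <- extract_envelope(st, srate, 250)
  expect_equal(env3$values, env2$values, tolerance = 1e-9)
})

test_that("target excision removes [onset, onset+1s) and merges overlaps", {
  srate <- 250
  rec <- toy_recording(3, 60, srate, c("Fz", "Cz", "Pz"))
  env <- seq_len(ncol(rec$data)) / srate
  # one alarm at 10 s in a 60 s record -> segments [0,10) and [11,60)
  ev <- toy_events(10, "alarm", "narrow")
  ss <- excise_targets(rec, env, ev)
  expect_length(ss$segments, 2)
  expect_equal(ss$starts_s, c(0, 11))
  expect_equal(ss$total_s, 59, tolerance = 2 / srate)
  # excised envelope samples really come from outside the zone
  expect_true(all(ss$segments[[2]]$env >= 11))
  # no targets -> single full-length segment
  ev0 <- toy_events(10, "instruction", "narrow")
  ss0 <- excise_targets(rec, env, ev0)
  expect_length(ss0$segments, 1)
  # alarms at 10.0 and 10.5 merge into one gap [10.0, 11.5)
  ev2 <- toy_events(c(10, 10.5), "alarm", "narrow")
  ss2 <- excise_targets(rec, env, ev2)
  expect_length(ss2$segments, 2)
  expect_equal(ss2$starts_s[2], 11.5)
  # beep events are excised too
  ev3 <- toy_events(c(10), "beep", "narrow")
  expect_length(excise_targets(rec, env, ev3)$segments, 2)
})

test_that("length equalization drops shortest segments from the longer condition", {
  mk <- function(lens) {
    segs <- lapply(lens, function(L)
      list(eeg = matrix(0, 2, L * 250), env = numeric(L * 250)))
    structure(list(segments = segs, srate_hz = 250, total_s = sum(lens),
                   starts_s = seq_along(lens), labels = c("a", "b")),
              class = "segment_set")
  }
  # equal totals unchanged; tol larger than difference unchanged
  eq <- equalize_lengths(mk(c(100, 50)), mk(c(75, 75)), 60)
  expect_equal(eq$narrow$total_s, 150)
  expect_equal(eq$wide$total_s, 150)
  # 120 s surplus with segments {90, 40, 20, 60, 30}: greedy drops the
  # shortest remaining from the longer side until the difference < 60
  nw <- mk(c(90, 40, 20, 60, 30))   # 240 total
  wd <- mk(c(60, 60))               # 120 total
  out <- equalize_lengths(nw, wd, 60)
  expect_lt(abs(out$narrow$total_s - out$wide$total_s), 60)
  # greedy simulation: drop 20 (diff 100), then 30 (diff 70), then 40 (diff 30)
  expect_equal(out$narrow$total_s, 150)
  expect_equal(attr(out$narrow, "dropped"), c(3, 5, 2))
  expect_error(equalize_lengths(mk(300), mk(10), 20), "emptying")
})

test_that("EEG scaling multiplies blocks and propagates into the model record", {
  ss <- toy_segset(matrix(1, 2, 500), rnorm(500))
  expect_equal(scale_eeg(ss, 1)$segments[[1]]$eeg, matrix(1, 2, 500))
  sc <- scale_eeg(ss, 0.0313)
  expect_true(all(sc$segments[[1]]$eeg == 0.0313))
  m <- fit_forward_trf(sc, c(-0.04, 0.04), 0.1)
  expect_equal(m$scale_applied, 0.0313)
  expect_error(scale_eeg(ss, -1), "positive")
})

test_that("ridge forward model matches the dense normal-equation oracle at lambda 0", {
  set.seed(10)
  srate <- 250
  n <- 30 * srate
  env <- rnorm(n)
  k <- 0.5 * sin(seq(0, 3 * pi, length.out = 26))
  # explicit zero-padded convolution (the segment's own generating model)
  conv_zp <- function(env, k) {
    y <- numeric(length(env))
    for (j in seq_along(k)) {
      src <- seq_along(env) - (j - 1)
      ok <- src >= 1
      y[ok] <- y[ok] + k[j] * env[src[ok]]
    }
    y
  }
  eeg <- rbind(conv_zp(env, k), conv_zp(env, rev(k) * 2))
  ss <- toy_segset(eeg, env, srate)
  lags <- seq.int(round(-0.2 * srate), round(0.8 * srate))
  m <- fit_forward_trf(ss, c(-0.2, 0.8), 0)

  # independent dense construction: explicit lagged matrix, direct solve
  Xd <- sapply(lags, function(l) {
    out <- numeric(n)
    src <- seq_len(n) - l
    ok <- src >= 1 & src <= n
    out[ok] <- env[src[ok]]
    out
  })
  Xd <- cbind(Xd, 1)
  Wd <- solve(crossprod(Xd), crossprod(Xd, t(eeg)))
  rel <- max(abs(m$weights - Wd[seq_along(lags), ])) / max(abs(Wd))
  expect_lt(rel, 1e-8)

  # the known kernel is recovered at the causal lags
  i0 <- match(0, lags)
  expect_equal(m$weights[i0 + seq_along(k) - 1, 1], as.numeric(k),
               tolerance = 1e-6)
})

test_that("the lag axis spans round(lo*fs)..round(hi*fs) inclusive and ridge shrinks", {
  set.seed(11)
  ss <- toy_segset(matrix(rnorm(2 * 2500), 2), rnorm(2500), 250)
  m <- fit_forward_trf(ss, c(-0.2, 0.8), 0.1)
  expect_equal(length(m$lags_s), 251)
  expect_equal(range(m$lags_s), c(-0.2, 0.8))
  norms <- sapply(c(0.1, 10, 1000, 1e5), function(l)
    sqrt(sum(fit_forward_trf(ss, c(-0.2, 0.8), l)$weights^2)))
  expect_true(all(diff(norms) < 0))
  # weights scale linearly with the EEG at lambda = 0 (exact linearity)
  ss2 <- toy_segset(ss$segments[[1]]$eeg * 3, ss$segments[[1]]$env, 250)
  expect_equal(fit_forward_trf(ss2, c(-0.2, 0.8), 0)$weights,
               fit_forward_trf(ss, c(-0.2, 0.8), 0)$weights * 3,
               tolerance = 1e-8)
})

test_that("TRF baseline correction zeroes the baseline mean and is idempotent", {
  set.seed(12)
  ss <- toy_segset(matrix(rnorm(2 * 2500), 2), rnorm(2500), 250)
  m <- fit_forward_trf(ss, c(-0.2, 0.8), 0.1)
  m$weights[, 1] <- m$weights[, 1] + 5     # constant offset on one channel
  b <- baseline_trf(m, c(-0.1, 0))
  bi <- b$lags_s >= -0.1 & b$lags_s <= 0
  expect_equal(colMeans(b$weights[bi, ]), c(0, 0), tolerance = 1e-12)
  expect_equal(baseline_trf(b, c(-0.1, 0))$weights, b$weights,
               tolerance = 1e-12)
  # constant weight rows vanish entirely
  m2 <- m; m2$weights[] <- 3
  expect_equal(max(abs(baseline_trf(m2, c(-0.1, 0))$weights)), 0)
})

test_that("GFP is the population SD across channels", {
  W <- cbind(rep(1, 5), rep(-1, 5))
  m <- structure(list(weights = W, lags_s = seq(0, 0.016, by = 0.004)),
                 class = "trf_model")
  expect_equal(as.numeric(gfp(m)), rep(1, 5))          # closed form
  expect_equal(as.numeric(gfp(cbind(W, W))), rep(1, 5))
  # identical channels -> zero
  expect_equal(as.numeric(gfp(cbind(rep(2, 5), rep(2, 5)))), rep(0, 5))
  # channel permutation invariance; common offsets at a lag shift all
  # channels together and leave GFP unchanged
  set.seed(13)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(gfp(X[, c(3, 1, 4, 2)]), gfp(X))
  expect_equal(gfp(X + 100), gfp(X), tolerance = 1e-9)
  expect_error(gfp(matrix(1, 5, 1)), "2 channels")
})

test_that("FWHM windows bracket the half-maximum crossings of a triangular bump", {
  lags <- seq(0, 0.45, by = 0.004)
  h <- 2
  tri <- pmax(0, h * (1 - abs(lags - 0.2) / 0.1))   # peak at 0.2, base 0.1
  g <- tri
  out <- individual_fwhm_window(g, g, c(0, 0.45), lags_s = lags)
  expect_equal(out$peak_s, 0.2, tolerance = 1e-9)
  # half maximum h/2 crossed at 0.15 and 0.25
  expect_equal(out$window, c(0.152, 0.248), tolerance = 0.004 + 1e-9)
  # never below half max inside the window -> clipped to the full window
  out2 <- individual_fwhm_window(rep(1, length(lags)), rep(1, length(lags)),
                                 c(0.1, 0.3), lags_s = lags)
  expect_equal(out2$window, c(0.1, 0.3), tolerance = 0.004)
  # peak at the window edge clips on that side
  ramp <- lags
  out3 <- individual_fwhm_window(ramp, ramp, c(0.1, 0.3), lags_s = lags)
  expect_equal(out3$peak_s, 0.3, tolerance = 0.004)
  expect_equal(out3$window[2], 0.3, tolerance = 0.004)
  # non-positive peak degenerates to the single peak sample
  out4 <- individual_fwhm_window(-tri - 1, -tri - 1, c(0, 0.45), lags_s = lags)
  expect_true(out4$degenerate)
})

test_that("window GFP means average each condition over the shared window", {
  lags <- seq(0, 0.45, by = 0.004)
  gn <- rep(2, length(lags)); gw <- rep(3, length(lags))
  m <- window_gfp_means(list(narrow = gn, wide = gw), c(0.1, 0.2),
                        lags_s = lags)
  expect_equal(m, c(narrow = 2, wide = 3))
  expect_equal(unname(diff(window_gfp_means(list(narrow = gn, wide = gn),
                                            c(0, 0.45), lags_s = lags))), 0)
  # fixed group-window variant is the same computation on a fixed interval
  grp <- window_gfp_means(list(narrow = gn, wide = gw), c(0, 0.45),
                          lags_s = lags)
  expect_equal(unname(grp), c(2, 3))
})
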