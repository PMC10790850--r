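test_that("FIR filtering removes DC, keeps the passband, kills the stopband", {
  srate <- 200
  t <- seq(0, 60 - 1 / srate, by = 1 / srate)
  interior <- seq(round(20 * srate), round(40 * srate))

  # DC offset through the 0.1 Hz high-pass
  rec <- new_recording(matrix(5 + 0 * t, 1), srate, "a")
  hp <- fir_filter(rec, hp_edge_hz = 0.1)
  expect_lt(abs(mean(hp$data[1, interior])), 0.05)

  # 40 Hz sine through the 30 Hz low-pass: attenuation beyond the design's
  # stopband spec (Hamming window: > 50 dB)
  rec40 <- new_recording(matrix(sin(2 * pi * 40 * t), 1), srate, "a")
  lp <- fir_filter(rec40, lp_edge_hz = 30)
  d <- design_fir(30, "low", srate)
  H40 <- abs(sum(d$coef * exp(-2i * pi * 40 * seq_along(d$coef) / srate)))
  amp <- max(abs(lp$data[1, interior]))
  expect_lt(amp, 10^(-50 / 20))
  expect_lt(amp, H40 * 1.1 + 1e-6)

  # 10 Hz sine through both filters: amplitude preserved within 1%
  rec10 <- new_recording(matrix(sin(2 * pi * 10 * t), 1), srate, "a")
  bp <- fir_filter(rec10, hp_edge_hz = 0.1, lp_edge_hz = 30)
  expect_equal(max(abs(bp$data[1, interior])), 1, tolerance = 0.01)

  expect_error(fir_filter(rec10, lp_edge_hz = 120), "Nyquist")
  expect_error(fir_filter(rec10), "at least one")
})

test_that("polyphase resampling halves counts and preserves in-band content", {
  srate <- 500
  t <- seq(0, 20 - 1 / srate, by = 1 / srate)
  rec <- new_recording(matrix(sin(2 * pi * 10 * t), 1), srate, "a")
  down <- resample_recording(rec, 250)
  expect_lte(abs(ncol(down$data) - length(t) / 2), 1)
  expect_equal(down$srate_hz, 250)
  # FFT peak stays at 10 Hz with amplitude within 1%
  interior <- seq(1000, 4000)
  x <- down$data[1, interior]
  sp <- Mod(fft(x * signal::hanning(length(x))))
  f <- (seq_along(x) - 1) * 250 / length(x)
  expect_equal(f[which.max(sp[f < 125])], 10, tolerance = 0.1)
  expect_equal(max(abs(x)), 1, tolerance = 0.01)
  # identity and error paths
  expect_identical(resample_recording(rec, 500)$data, rec$data)
  expect_error(resample_recording(rec, 1000), "upsampling")
})

test_that("filter and resample commute with channel permutation", {
  set.seed(1)
  mont <- default_montage()[1:4, ]
  data <- matrix(rnorm(4 * 2000), 4)
  rec <- new_recording(data, 500, mont$label, mont)
  perm <- c(3, 1, 4, 2)
  rec_p <- new_recording(data[perm, ], 500, mont$label[perm], mont[perm, ])
  out <- resample_recording(fir_filter(rec, 1, 30), 250)
  out_p <- resample_recording(fir_filter(rec_p, 1, 30), 250)
  expect_equal(out_p$data, out$data[perm, ], tolerance = 1e-12)
})

test_that("bad-channel flagging finds flat lines and variance outliers only", {
  set.seed(2)
  mont <- default_montage()
  data <- matrix(rnorm(24 * 5000, sd = 8), 24)
  rec <- new_recording(data, 250, mont$label, mont)
  expect_length(flag_bad_channels(rec), 0)
  data2 <- data
  data2[3, ] <- 0                       # flat
  data2[7, ] <- rnorm(5000, sd = 80)    # 10x noise SD
  rec2 <- new_recording(data2, 250, mont$label, mont)
  flags <- flag_bad_channels(rec2, var_z_thresh = 3)
  expect_setequal(flags, mont$label[c(3, 7)])
  data3 <- matrix(0, 24, 100)
  data3[1:2, ] <- rnorm(200)
  expect_error(flag_bad_channels(new_recording(data3, 250, mont$label, mont)),
               "half")
})

test_that("spherical-spline interpolation reproduces constants and smooth fields", {
  mont <- default_montage()
  n <- 100
  # constant field: interpolated channel equals the constant
  rec <- new_recording(matrix(3.7, 24, n), 250, mont$label, mont)
  out <- interpolate_spherical(rec, "Cz")
  expect_equal(out$data[match("Cz", mont$label), ], rep(3.7, n),
               tolerance = 1e-6)
  # empty bads -> identity
  expect_identical(interpolate_spherical(rec, character(0)), rec)

  # leave-one-out on a smooth dipolar field: correlation with truth > 0.95
  set.seed(3)
  pos <- as.matrix(mont[, c("x", "y", "z")])
  field <- function(src) exp(-acos(pmin(1, pos %*% src))^2)
  src1 <- c(0, 0.5, 0.866); src2 <- c(0.5, -0.5, 0.7071)
  src2 <- src2 / sqrt(sum(src2^2))
  amp <- cbind(rnorm(n), rnorm(n))
  data <- field(src1) %*% t(amp[, 1]) + field(src2) %*% t(amp[, 2])
  rec2 <- new_recording(data, 250, mont$label, mont)
  for (ch in c("Cz", "P3", "F4")) {
    got <- interpolate_spherical(rec2, ch)
    i <- match(ch, mont$label)
    expect_gt(cor(got$data[i, ], data[i, ]), 0.95)
    expect_equal(got$data[-i, ], data[-i, ])   # good channels untouched
  }
})

test_that("linked-mastoid referencing zeroes the mastoid mean and keeps differences", {
  set.seed(4)
  mont <- default_montage()
  data <- matrix(rnorm(24 * 500), 24)
  rec <- new_recording(data, 250, mont$label, mont)
  ref <- rereference_linked_mastoids(rec)
  im <- match(c("TP9", "TP10"), mont$label)
  expect_equal(colMeans(ref$data[im, ]), rep(0, 500), tolerance = 1e-12)
  expect_equal(ref$reference, "linked-mastoid")
  # re-applying subtracts (an all-zero) mastoid mean: idempotent
  ref2 <- rereference_linked_mastoids(ref)
  expect_equal(ref2$data, ref$data, tolerance = 1e-12)
  # channel differences are reference-invariant
  expect_equal(ref$data[1, ] - ref$data[2, ], data[1, ] - data[2, ],
               tolerance = 1e-12)
  rec_no <- new_recording(data[1:3, ], 250, mont$label[1:3], mont[1:3, ])
  expect_error(rereference_linked_mastoids(rec_no), "TP9")
})

test_that("marker-delay correction shifts stimulus onsets by the constant delay", {
  ev <- toy_events(c(1, 2.5))
  out <- correct_marker_delay(ev, 0.019)
  expect_equal(out$onset_s, c(1.019, 2.519))
  expect_identical(correct_marker_delay(ev, 0)$onset_s, ev$onset_s)
  expect_equal(nrow(correct_marker_delay(empty_events(), 0.019)), 0)
})

test_that("epoch rejection flags the right epochs and is scale-equivariant", {
  set.seed(5)
  arr <- array(rnorm(50 * 4 * 100), c(50, 4, 100))
  # identical epochs: zero variance handled, none rejected
  same <- array(rep(arr[1, , ], each = 50), c(50, 4, 100))
  m0 <- reject_epochs(same, 2)
  expect_false(any(m0$rejected))

  # one epoch with 20x amplitude among 50 is rejected at 3 SD
  arr2 <- arr
  arr2[17, , ] <- arr2[17, , ] * 20
  m <- reject_epochs(arr2, 3)
  expect_true(m$rejected[17])
  expect_equal(sum(m$rejected), 1)
  expect_match(m$reason[17], "global|local")

  # infinite threshold rejects nothing
  expect_false(any(reject_epochs(arr2, Inf)$rejected))

  # multiplying all data by c > 0 yields the identical mask
  m_scaled <- reject_epochs(arr2 * 7.3, 3)
  expect_identical(m$rejected, m_scaled$rejected)
  expect_equal(attr(m, "channel_z"), attr(m_scaled, "channel_z"),
               tolerance = 1e-9)

  expect_error(reject_epochs(arr2[1:2, , , drop = FALSE], 3), "3 epochs")
})

test_that("ocular removal suppresses injected blinks and leaves clean data alone", {
  tr <- ground_truth(noise_sd_uv = 5, blink_rate_hz = 0.4)
  rec <- simulate_eeg(empty_events(), NULL, tr, duration_s = 60, seed = 6)
  # locate blink epochs from the (known) frontal channel before removal
  fp <- colMeans(rec$data[match(c("Fp1", "Fp2"), rec$labels), ])
  blink_mask <- fp > 40
  expect_gt(sum(blink_mask), 100)  # blinks were injected
  cleaned <- remove_ocular(rec)
  v_before <- var(fp[blink_mask])
  fp_after <- colMeans(cleaned$data[match(c("Fp1", "Fp2"), cleaned$labels), ])
  expect_lt(var(fp_after[blink_mask]) / v_before, 0.2)

  # blink-free data pass through nearly unchanged
  tr0 <- ground_truth(noise_sd_uv = 5, blink_rate_hz = 0)
  rec0 <- simulate_eeg(empty_events(), NULL, tr0, duration_s = 30, seed = 7)
  out0 <- remove_ocular(rec0)
  rel <- sqrt(sum((out0$data - rec0$data)^2) / sum(rec0$data^2))
  expect_lt(rel, 0.01)

  # a hook honoring the same contract replaces the stage
  marker <- function(r) { r$hooked <- TRUE; r }
  expect_true(remove_ocular(rec0, hook = marker)$hooked)
})

test_that("the fused preprocessing path equals the sequential stage chain", {
  tr <- ground_truth(noise_sd_uv = 6, blink_rate_hz = 0)
  rec <- simulate_eeg(toy_events(c(4, 9)), NULL, tr, duration_s = 20, seed = 8)
  cfg <- pipeline_config()
  fused <- preprocess_recording(rec, cfg)
  seq_rec <- rereference_linked_mastoids(remove_ocular(
    resample_recording(fir_filter(rec, cfg$hp_edge_hz, cfg$lp_edge_hz),
                       cfg$target_srate_hz)))
  expect_equal(fused$data, seq_rec$data, tolerance = 1e-8)
  expect_equal(attr(fused, "log")$order,
               c("filter", "resample", "interpolate", "ocular", "rereference"))
})
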