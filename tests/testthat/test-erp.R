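test_that("hit classification follows the 3-second window with press consumption", {
  ev <- toy_events(c(10, 11), "alarm", "narrow")
  # press at onset + 2.9 s is a hit
  out <- classify_hits(ev[1, ], 12.9, 3)
  expect_true(out$is_hit[1])
  expect_equal(out$response_onset_s[1], 12.9)
  # press at onset + 3.001 s misses
  expect_false(classify_hits(ev[1, ], 13.001, 3)$is_hit[1])
  # boundary press exactly at onset + 3 s counts
  expect_true(classify_hits(ev[1, ], 13.0, 3)$is_hit[1])
  # press exactly at onset does not
  expect_false(classify_hits(ev[1, ], 10.0, 3)$is_hit[1])

  # two targets 1 s apart, one press after the second: earliest unconsumed
  # target whose window contains the press gets it
  both <- classify_hits(ev, 11.5, 3)
  expect_true(both$is_hit[1])
  expect_false(both$is_hit[2])
  # two presses serve both targets
  both2 <- classify_hits(ev, c(11.5, 12.2), 3)
  expect_true(all(both2$is_hit))
  expect_equal(both2$response_onset_s, c(11.5, 12.2))
})

test_that("epoching uses the half-open grid and removes the baseline", {
  srate <- 250
  rec <- toy_recording(3, 10, srate, c("Fz", "Cz", "Pz"))
  rec$data[2, ] <- 4.2               # constant channel
  ev <- toy_events(c(2, 5))
  ep <- make_epochs(rec, ev, c(-0.2, 0.8), c(-0.2, 0))
  expect_equal(dim(ep$data), c(2, 3, 250))   # 1.0 s at 250 Hz -> 250 samples
  # constant channel is zero after baselining
  expect_equal(max(abs(ep$data[, 2, ])), 0, tolerance = 1e-12)
  # per-trial per-channel baseline means vanish
  bidx <- ep$times < 0
  expect_lt(max(abs(apply(ep$data[, , bidx], c(1, 2), mean))), 1e-10)
  # event too close to the edge is dropped and logged
  ev2 <- toy_events(c(0.05, 5))
  ep2 <- make_epochs(rec, ev2, c(-0.2, 0.8), c(-0.2, 0))
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(attr(ep2, "dropped"), 1L)
})

test_that("baseline correction is idempotent and amplitudes are linear in the data", {
  srate <- 250
  rec <- toy_recording(3, 10, srate, c("Fz", "Cz", "Pz"))
  ev <- toy_events(c(2, 5))
  ep1 <- make_epochs(rec, ev, c(-0.2, 0.8), c(-0.2, 0))
  rec2 <- rec; rec2$data <- rec$data * 3
  ep3 <- make_epochs(rec2, ev, c(-0.2, 0.8), c(-0.2, 0))
  expect_equal(ep3$data, ep1$data * 3, tolerance = 1e-12)
  a1 <- trial_window_means(ep1, c(0.3, 0.4), c("Fz", "Cz"), "p")
  a3 <- trial_window_means(ep3, c(0.3, 0.4), c("Fz", "Cz"), "p")
  expect_equal(a3$amplitude_uv, a1$amplitude_uv * 3, tolerance = 1e-12)
})

test_that("the peak-search waveform weights conditions, not trials", {
  arr_n <- array(1, c(10, 2, 50))        # flat +1, 10 trials
  arr_w <- array(-1, c(100, 2, 50))      # flat -1, 100 trials
  en <- toy_epochs(arr_n, condition = "narrow")
  ew <- toy_epochs(arr_w, condition = "wide")
  w <- mean_erp_for_peaks(en, ew, c("ch1", "ch2"))
  expect_equal(as.numeric(w), rep(0, 50))       # unweighted condition average
  # identical conditions equal either condition mean
  w2 <- mean_erp_for_peaks(en, toy_epochs(array(1, c(3, 2, 50)),
                                          condition = "wide"), c("ch1", "ch2"))
  expect_equal(as.numeric(w2), rep(1, 50))
  expect_error(mean_erp_for_peaks(NULL, ew, "ch1"), "narrow")
})

test_that("component windows come from the signed extremum with clipping and ties", {
  times <- seq(-0.2, 0.795, by = 0.005)   # grid contains 0.1, 0.3, 0.35, 0.4
  spec <- component_spec("P3")
  # P3 peak at 350 ms -> window [300, 400] ms
  wave <- exp(-(times - 0.35)^2 / (2 * 0.05^2))
  attr(wave, "times") <- times
  got <- find_component_window(wave, spec)
  expect_equal(got$peak_s, 0.35, tolerance = 1e-9)
  expect_equal(got$window, c(0.30, 0.40), tolerance = 1e-9)
  # N1 peak at 100 ms -> window [75, 125] ms
  n1 <- -exp(-(times - 0.1)^2 / (2 * 0.02^2))
  attr(n1, "times") <- times
  gn <- find_component_window(n1, component_spec("N1"))
  expect_equal(gn$peak_s, 0.1, tolerance = 1e-9)
  expect_equal(gn$window, c(0.075, 0.125), tolerance = 1e-9)
  # monotone waveform: edge extremum accepted with a warning
  mono <- times
  attr(mono, "times") <- times
  expect_warning(ge <- find_component_window(mono, spec), "edge")
  expect_equal(ge$peak_s, 0.4, tolerance = 1e-9)
  # ties resolve to the earliest latency
  flat <- rep(1, length(times)); attr(flat, "times") <- times
  expect_warning(gt <- find_component_window(flat, spec), "edge")
  expect_equal(gt$peak_s, 0.3, tolerance = 1e-9)
  bad <- wave; bad[10] <- NaN
  expect_error(find_component_window(bad, spec), "finite")
})

test_that("trial window means recover constants and the closed-form ramp mean", {
  srate <- 250
  nt <- 250
  times <- seq(-0.2, by = 1 / srate, length.out = nt)
  a <- 1.5; b <- -2
  ramp <- a + b * times
  arr <- array(NA_real_, c(4, 2, nt))
  arr[, 1, ] <- 3.3                                  # constant channel
  arr[, 2, ] <- rep(ramp, each = 4)                  # linear ramp channel
  ep <- toy_epochs(arr, srate)
  got <- trial_window_means(ep, c(0.2, 0.6), c("ch1", "ch2"), "p")
  expect_equal(nrow(got), 4 * 2)                     # n trials x k channels
  expect_equal(got$amplitude_uv[got$channel == "ch1"], rep(3.3, 4))
  # ramp mean over [t0, t1] is a + b (t0 + t1) / 2 within one sample
  expect_equal(got$amplitude_uv[got$channel == "ch2"],
               rep(a + b * (0.2 + 0.6) / 2, 4), tolerance = abs(b) / srate)
  expect_error(trial_window_means(ep, c(0.2, 0.6), "nope"), "empty|unknown")
})

test_that("noiseless pipeline puts the P3 window on the injected peak and recovers contrast signs", {
  tr0 <- ground_truth(noise_sd_uv = 0, blink_rate_hz = 0)
  spec <- component_spec("P3")
  amps <- list()
  for (cond in c("narrow", "wide")) {
    s <- toy_events(seq(5, 29, by = 4), "alarm", cond)
    rec <- simulate_eeg(s, NULL, tr0, duration_s = 32, seed = 1)
    ep <- make_epochs(rec, s, c(-0.2, 0.8), c(-0.2, 0))
    amps[[cond]] <- ep
  }
  wav <- mean_erp_for_peaks(amps$narrow, amps$wide, spec$channels)
  got <- find_component_window(wav, spec)
  # detected peak latency equals the injected kernel peak exactly
  kern <- attnscape:::erp_kernels("alarm", TRUE, tr0, 500)
  ktimes <- seq(0, 0.7, by = 1 / 500)
  expect_equal(got$peak_s, ktimes[which.max(kern$p)], tolerance = 1e-12)
  expect_equal(got$peak_s, 0.35, tolerance = 1e-12)
  # alarm contrast (wide - narrow) negative in every noiseless run
  m_n <- mean(trial_window_means(amps$narrow, got$window, spec$channels)$amplitude_uv)
  m_w <- mean(trial_window_means(amps$wide, got$window, spec$channels)$amplitude_uv)
  expect_lt(m_w, m_n)
  expect_equal(m_w - m_n, -4 * mean(attnscape:::gaussian_topography(
    default_montage(), "Pz", 0.9)[spec$channels]) *
      mean(exp(-(seq(0.3, 0.4, by = 1/500) - 0.35)^2 / (2 * 0.06^2))),
    tolerance = 0.05)

  # beep contrast positive in wide
  for (cond in c("narrow", "wide")) {
    s <- toy_events(seq(5, 29, by = 4), "beep", cond)
    s$direction_deg <- 0
    rec <- simulate_eeg(s, NULL, tr0, duration_s = 32, seed = 1)
    amps[[cond]] <- make_epochs(rec, s, c(-0.2, 0.8), c(-0.2, 0))
  }
  wavb <- mean_erp_for_peaks(amps$narrow, amps$wide, spec$channels)
  gotb <- find_component_window(wavb, spec)
  mb_n <- mean(trial_window_means(amps$narrow, gotb$window, spec$channels)$amplitude_uv)
  mb_w <- mean(trial_window_means(amps$wide, gotb$window, spec$channels)$amplitude_uv)
  expect_gt(mb_w, mb_n)
})
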