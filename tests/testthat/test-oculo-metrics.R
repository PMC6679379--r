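mk_trace <- function(eye, head = NULL, kind = "avor",
                     stimulus = list(freq_hz = 0.5, peak_vel_dps = 30)) {
  n <- length(eye)
  t <- seq(0, by = 1e-3, length.out = n)
  if (is.null(head)) head <- numeric(n)
  vestisyn:::new_trace(t, head, eye, kind, stimulus, 0L)
}

test_that("preprocessing differentiates to the analytic velocity", {
  t <- seq(0, 10, by = 1e-3)
  A <- 8
  tr <- mk_trace(A * sin(2 * pi * 0.5 * t))
  tr <- preprocess_trace(tr)
  mid <- tr$time > 1 & tr$time < 9
  amp <- max(abs(tr$eye_vel[mid]))
  expect_equal(amp, 2 * pi * 0.5 * A, tolerance = 1e-3)
  # constant position: zero velocity over the analysed span (the filter's
  # startup/ending transients live inside the trimmed edge guard)
  trc <- preprocess_trace(mk_trace(rep(3, 5000)))
  span <- trc$time >= 0.2 & trc$time <= max(trc$time) - 0.2
  expect_lt(max(abs(trc$eye_vel[span])), 1e-4)
})

test_that("the 40 Hz low-pass attenuates a 60 Hz component", {
  t <- seq(0, 5, by = 1e-3)
  tr <- preprocess_trace(mk_trace(sin(2 * pi * 60 * t)))
  mid <- tr$time > 1 & tr$time < 4
  gain60 <- max(abs(tr$eye_pos_f[mid]))  # input amplitude 1
  expect_lt(gain60, 0.5)
  # passband is preserved
  tr2 <- preprocess_trace(mk_trace(sin(2 * pi * 1 * t)))
  expect_gt(max(abs(tr2$eye_pos_f[mid])), 0.99)
})

test_that("non-uniform sampling is rejected", {
  tr <- mk_trace(rnorm(1000))
  tr$time[500] <- tr$time[500] + 5e-3
  expect_error(preprocess_trace(tr), "sampling error")
})

test_that("quick-phase segmentation finds exactly the injected beats", {
  pr <- oculo_preset("svn", gain = 0, beat_rate_bpm = 12,
                     slow_phase_vel_dps = 3, noise_sd_deg = 0)
  tr <- preprocess_trace(simulate_spontaneous(pr, duration = 100, seed = 3))
  seg <- segment_quick_phases(tr)
  expect_identical(nrow(seg$excluded), tr$n_beats)
  # a saccade-free sinusoid has no exclusions
  t <- seq(0, 10, by = 1e-3)
  tr2 <- preprocess_trace(mk_trace(8 * sin(2 * pi * 0.5 * t)))
  expect_identical(nrow(segment_quick_phases(tr2)$excluded), 0L)
  expect_error(segment_quick_phases(tr, vel_threshold = -5), "threshold")
})

test_that("retained and excluded intervals partition the analysed span", {
  pr <- load_oculo_preset("ttk24h")
  tr <- preprocess_trace(simulate_spontaneous(pr, duration = 80, seed = 9))
  seg <- segment_quick_phases(tr)
  iv <- rbind(seg$retained, seg$excluded)
  iv <- iv[order(iv$start_s), ]
  expect_true(all(iv$end_s >= iv$start_s))
  expect_lt(abs(iv$start_s[1] - seg$span_s[1]), 2e-3)
  expect_lt(abs(iv$end_s[nrow(iv)] - seg$span_s[2]), 2e-3)
  gaps <- iv$start_s[-1] - iv$end_s[-nrow(iv)]
  expect_true(all(gaps >= 0 & gaps <= 2e-3))  # contiguous cover
})

test_that("aVOR gain is recovered across the sweep and is scale invariant", {
  for (g in c(0.2, 0.55, 0.9)) {
    pr <- oculo_preset("sweep", gain = g, noise_sd_deg = 0.1)
    got <- vapply(1:2, function(s) {
      tr <- preprocess_trace(simulate_avor(pr, freq = 0.5, duration = 16,
                                           seed = s))
      avor_gain(tr, segment_quick_phases(tr))$gain
    }, numeric(1))
    expect_equal(mean(got), g, tolerance = 0.02)
  }
  # ideal gain-1 trace
  pr1 <- oculo_preset("ideal", gain = 1, noise_sd_deg = 0)
  tr <- preprocess_trace(simulate_avor(pr1, freq = 0.5, duration = 16,
                                       seed = 1))
  res <- avor_gain(tr, segment_quick_phases(tr))
  expect_equal(res$gain, 1, tolerance = 1e-3)
  expect_equal(res$phase_deg, 0, tolerance = 0.5)
  # scaling both signals leaves the gain unchanged
  tr2 <- tr
  tr2$eye_pos <- 3.7 * tr$eye_pos
  tr2$head_pos <- 3.7 * tr$head_pos
  tr2 <- preprocess_trace(tr2)
  expect_equal(avor_gain(tr2, segment_quick_phases(tr2))$gain, res$gain,
               tolerance = 1e-6)
})

test_that("segmentation leaves saccade-free gains essentially unchanged", {
  pr <- oculo_preset("clean", gain = 0.6, noise_sd_deg = 0.05)
  tr <- preprocess_trace(simulate_avor(pr, freq = 0.5, duration = 16,
                                       seed = 2))
  seg <- segment_quick_phases(tr)
  full <- seg
  full$retained <- data.frame(start_s = seg$span_s[1], end_s = seg$span_s[2])
  full$excluded <- full$excluded[0, ]
  g_seg <- avor_gain(tr, seg)$gain
  g_full <- avor_gain(tr, full)$gain
  expect_lt(abs(g_seg - g_full) / g_full, 0.01)
})

test_that("too little retained data is an insufficient-data error", {
  pr <- oculo_preset("short", gain = 0.5, noise_sd_deg = 0)
  tr <- preprocess_trace(simulate_avor(pr, freq = 0.2, duration = 11,
                                       seed = 1))
  seg <- segment_quick_phases(tr)  # ~2 cycles at 0.2 Hz
  expect_error(avor_gain(tr, seg), "insufficient")
  tro <- preprocess_trace(simulate_ovar(load_oculo_preset("baseline"),
                                        duration = 15, seed = 1))
  expect_error(mor_bias(tro, segment_quick_phases(tro)), "insufficient")
})

test_that("MOR bias recovery is accurate in the noiseless limit", {
  pr <- oculo_preset("mor", gain = 0, bias_dps = 5, mor_modulation_dps = 3,
                     noise_sd_deg = 0)
  tr <- preprocess_trace(simulate_ovar(pr, rot_vel = 50, duration = 40,
                                       seed = 1))
  res <- mor_bias(tr, segment_quick_phases(tr))
  expect_equal(res$bias_dps, 5, tolerance = 0.05)
  expect_equal(res$modulation_dps, 3, tolerance = 0.15)
})

test_that("nystagmus rate counts beats per minute with drift direction", {
  pr <- oculo_preset("svn", gain = 0, beat_rate_bpm = 10,
                     slow_phase_vel_dps = 2, noise_sd_deg = 0,
                     drift_side = -1)
  tr <- preprocess_trace(simulate_spontaneous(pr, duration = 120, seed = 4))
  res <- svn_rate(tr, segment_quick_phases(tr))
  expect_equal(res$beats_per_min, 10, tolerance = 1e-9)
  expect_identical(res$slow_phase_direction, "ipsilesional")
  # contralesional drift flips the call
  pr2 <- oculo_preset("svn2", gain = 0, beat_rate_bpm = 10,
                      slow_phase_vel_dps = 2, noise_sd_deg = 0,
                      drift_side = 1)
  tr2 <- preprocess_trace(simulate_spontaneous(pr2, duration = 120, seed = 4))
  expect_identical(svn_rate(tr2, segment_quick_phases(tr2))$slow_phase_direction,
                   "contralesional")
  # beat-free drift: zero rate
  pr0 <- oculo_preset("drift", gain = 0, beat_rate_bpm = 0,
                      slow_phase_vel_dps = 1, noise_sd_deg = 0)
  tr0 <- preprocess_trace(simulate_spontaneous(pr0, duration = 65, seed = 1))
  expect_equal(svn_rate(tr0, segment_quick_phases(tr0))$beats_per_min, 0)
})
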