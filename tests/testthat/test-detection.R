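test_that("band-pass responses meet the pass/stop contracts", {
  sr <- 14000
  t <- seq(0, 2, by = 1 / sr)
  ss <- 5000:23000  # steady-state portion
  y10 <- bandpass(trace_recording(sin(2 * pi * 10 * t), sr),
                  lfp_filter())$voltages[1, ]
  expect_lt(abs(20 * log10(max(abs(y10[ss])))), 1)          # within 1 dB
  y50 <- bandpass(trace_recording(sin(2 * pi * 50 * t), sr),
                  mua_filter())$voltages[1, ]
  expect_lt(20 * log10(max(abs(y50[ss]))), -40)             # >= 40 dB down
  ydc <- bandpass(trace_recording(rep(5, length(t)), sr),
                  lfp_filter())$voltages[1, ]
  expect_lt(max(abs(ydc[ss])) / 5, 0.05)
  expect_error(bandpass(trace_recording(t, sr), filter_spec(300, 8000)),
               "Nyquist")
})

test_that("filtering preserves shape and is zero-phase", {
  sr <- 2000
  t <- seq(0, 4, by = 1 / sr)
  x <- sin(2 * pi * 20 * t)
  y <- bandpass(trace_recording(x, sr), lfp_filter())$voltages[1, ]
  ss <- 2000:6000
  # peak positions unshifted: cross-correlation maximal at zero lag
  cc <- stats::ccf(x[ss], y[ss], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("robust noise SD estimation resists event contamination", {
  expect_identical(estimate_noise_sd(rep(0, 200)), 0)
  set.seed(3)
  x <- rnorm(14000, 0, 10)
  expect_lt(abs(estimate_noise_sd(x) - 10) / 10, 0.05)
  spiky <- x
  idx <- sample.int(14000, 140)
  spiky[idx] <- spiky[idx] + 200
  expect_lt(abs(estimate_noise_sd(spiky) - 10) / 10, 0.10)
  expect_gt(stats::sd(spiky), 15)
  expect_error(estimate_noise_sd(rnorm(50)), "100 samples")
})

test_that("hard-threshold LFP detection finds single deflections at the right time", {
  expect_identical(nrow(detect_lfp_events(trace_recording(rep(0, 5000), 1000))),
                   0L)
  fx <- deflection_recording(times = 2, amps = 200, dur = 0.5, sr = 1000)
  ev <- detect_lfp_events(fx$recording,
                          detection_params(lfp_threshold_uv = 100))
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$t_peak - fx$t_peak), 0.010)
})

test_that("refractory merging joins close deflections and keeps distant ones", {
  p <- detection_params(lfp_threshold_uv = 100, lfp_refractory = 0.5)
  far <- deflection_recording(times = c(1, 3), amps = c(200, 200),
                              dur = 0.08, sr = 1000)
  expect_identical(nrow(detect_lfp_events(far$recording, p)), 2L)
  near <- deflection_recording(times = c(1, 1.12), amps = c(200, 200),
                               dur = 0.08, sr = 1000)
  expect_identical(nrow(detect_lfp_events(near$recording, p)), 1L)
})

test_that("duration bounds discard too-short and too-long events", {
  p <- detection_params(lfp_threshold_uv = 100, lfp_min_duration = 0.05,
                        lfp_max_duration = 1)
  short <- deflection_recording(times = 1, amps = 300, dur = 0.04, sr = 1000)
  expect_identical(nrow(detect_lfp_events(short$recording, p)), 0L)
  long <- deflection_recording(times = 1, amps = 300, dur = 2.5, sr = 1000,
                               total_s = 5)
  expect_identical(nrow(detect_lfp_events(long$recording, p)), 0L)
})

test_that("PTSD detects noiseless templates with perfect timing", {
  expect_identical(nrow(detect_spikes_ptsd(
    trace_recording(rep(0, 30000), 14000))), 0L)
  out <- spike_fixture(seed = 7)
  fil <- bandpass(out$recording, mua_filter())
  spk <- detect_spikes_ptsd(fil, detection_params(spike_k = 8))
  m <- match_rate(spk, out$true_events, tol = 0.001)
  expect_identical(m$recall, 1)
  expect_identical(m$precision, 1)
})

test_that("sub-threshold templates yield no PTSD detections", {
  # in the MUA band a 40 uV background leaves ~27 uV of noise; at k = 20
  # the differential threshold (~540 uV) exceeds every injected template
  # (p2p <= ~190) and any local noise excursion
  out <- spike_fixture(seed = 5, sd = 40)
  fil <- bandpass(out$recording, mua_filter())
  spk <- detect_spikes_ptsd(fil, detection_params(spike_k = 20))
  expect_identical(nrow(spk), 0L)
})

test_that("detection is per-channel independent under channel permutation", {
  set.seed(12)
  g <- make_geometry(1, 4, 42)
  v <- matrix(rnorm(4 * 5000, 0, 3), 4, 5000)
  tt <- (seq_len(400) - 1) / 1000 - 0.2
  v[2, 1001:1400] <- v[2, 1001:1400] - 150 * exp(-tt^2 / (2 * (0.4 / 6)^2))
  v[4, 3001:3400] <- v[4, 3001:3400] - 180 * exp(-tt^2 / (2 * (0.4 / 6)^2))
  rec <- mea_recording(v, 1000, g)
  perm <- c(3L, 1L, 4L, 2L)
  rec_p <- mea_recording(v[perm, ], 1000, g)
  p <- detection_params(lfp_threshold_uv = 80)
  ev <- detect_lfp_events(rec, p)
  ev_p <- detect_lfp_events(rec_p, p)
  # same events, with channels mapped back through the permutation
  ev_p$channel <- perm[ev_p$channel + 1L] - 1L
  o1 <- order(ev$t_peak); o2 <- order(ev_p$t_peak)
  expect_equal(ev$channel[o1], ev_p$channel[o2])
  expect_equal(ev$t_peak[o1], ev_p$t_peak[o2])
})

test_that("scaling trace and threshold together leaves detections unchanged", {
  fx <- deflection_recording(times = c(1, 2.5), amps = c(150, 250),
                             dur = 0.3, sr = 1000, noise_sd = 2)
  p1 <- detection_params(lfp_threshold_uv = 80)
  p10 <- detection_params(lfp_threshold_uv = 800)
  ev1 <- detect_lfp_events(fx$recording, p1)
  rec10 <- mea_recording(fx$recording$voltages * 10, 1000,
                         fx$recording$geometry)
  ev10 <- detect_lfp_events(rec10, p10)
  expect_equal(ev1$t_on, ev10$t_on)
  expect_equal(ev1$t_off, ev10$t_off)
  expect_equal(ev10$amplitude_uv, 10 * ev1$amplitude_uv, tolerance = 1e-5)
})
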