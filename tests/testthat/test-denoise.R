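test_that("line-noise flagging isolates mains-dominated channels", {
  sr <- 1000
  t <- seq_len(10 * sr) / sr
  g <- make_geometry(1, 3, 42)
  set.seed(7)
  v <- rbind(20 * sin(2 * pi * 50 * t),          # pure mains
             rnorm(length(t), 0, 10),            # white
             rep(0, length(t)))                  # dead channel
  flags <- flag_line_noise(mea_recording(v, sr, g), denoise_config())
  expect_identical(unname(flags), c(TRUE, FALSE, FALSE))
  expect_error(flag_line_noise(trace_recording(rnorm(400), 1000)),
               ">= 1 s")
})

test_that("mechanical flagging needs a large simultaneous channel fraction", {
  sr <- 7000
  g <- make_geometry(8, 8, 42)
  set.seed(8)
  base <- matrix(rnorm(64 * sr * 2, 0, 5), 64, sr * 2)
  rec <- mea_recording(base, sr, g)
  expect_identical(nrow(flag_mechanical(rec)), 0L)

  out <- inject_noise(rec, noise_spec("MECHANICAL", channel_fraction = 0.8,
                                      amplitude_uv = 150, width_ms = 8,
                                      n_transients = 1L), seed = 3)
  w <- flag_mechanical(out$recording)
  expect_identical(nrow(w), 1L)
  t_inj <- min(out$registry$t_on)
  expect_lt(abs(w$t_start - t_inj), 0.02)  # within ~one window length

  few <- inject_noise(rec, noise_spec("MECHANICAL", channels = 0L,
                                      amplitude_uv = 150, width_ms = 8,
                                      n_transients = 1L), seed = 3)
  expect_identical(nrow(flag_mechanical(few$recording)), 0L)
})

test_that("inductive flagging follows shared readout-group waveforms", {
  sr <- 1000
  g <- make_geometry(4, 4, 42)   # readout groups = columns of 4
  set.seed(9)
  rec <- mea_recording(matrix(rnorm(16 * 8 * sr, 0, 5), 16, 8 * sr), sr, g)
  res0 <- flag_inductive(rec, mea_events(), denoise_config())
  expect_false(any(res0$flagged))
  expect_true(all(abs(res0$median_corr) < 0.3))

  out <- inject_noise(rec, noise_spec("INDUCTIVE", readout_groups = 2L,
                                      amplitude_uv = 30), seed = 4)
  res <- flag_inductive(out$recording, mea_events(), denoise_config())
  expect_true(res$flagged[res$readout_group == 2])
  expect_identical(sum(res$flagged), 1L)

  # single-channel groups are skipped, never flagged
  g1 <- make_geometry(1, 2, 42, readout_group = c(0L, 1L))
  rec1 <- mea_recording(matrix(rnorm(2 * 2000), 2, 2000), 1000, g1)
  res1 <- flag_inductive(rec1, mea_events(), denoise_config())
  expect_true(all(!res1$flagged))
  expect_true(all(is.na(res1$median_corr)))
})

test_that("independent white noise never looks inductive (repeated draws)", {
  sr <- 1000
  g <- make_geometry(4, 2, 42)
  for (s in 1:5) {
    set.seed(100 + s)
    rec <- mea_recording(matrix(rnorm(8 * 4 * sr, 0, 8), 8, 4 * sr), sr, g)
    res <- flag_inductive(rec, mea_events(), denoise_config())
    expect_false(any(res$flagged))
  }
})

test_that("calibration flagging catches offsets and saturation", {
  set.seed(10)
  g <- make_geometry(1, 3, 42)
  v <- rbind(rnorm(5000, 300, 10),   # large DC offset
             pmin(pmax(rnorm(5000, 0, 60), -50), 50),  # heavy clipping
             rnorm(5000, 0, 10))
  flags <- flag_calibration(mea_recording(v, 1000, g),
                            denoise_config(calibration_offset_threshold = 100,
                                           saturation_fraction_threshold = 0.05))
  expect_identical(unname(flags), c(TRUE, TRUE, FALSE))
  expect_gt(mean(v[2, ] == 50) + mean(v[2, ] == -50), 0.05)
})

test_that("events at the template medians are classified as signal", {
  sr <- 1000
  tt <- seq_len(300) / sr
  set.seed(11)
  wfs <- lapply(1:20, function(i)
    -runif(1, 180, 220) * exp(-(tt - 0.15)^2 / (2 * 0.03^2)) + rnorm(300, 0, 3))
  ev <- mea_events(1:20, rep(0:3, 5), rep("LFP", 20),
                   t_on = 1:20, t_peak = 1:20 + 0.15, t_off = 1:20 + 0.3,
                   amplitude_uv = vapply(wfs, function(w) max(w) - min(w), 0),
                   waveform = wfs, snippet_rate = sr)
  ef <- event_features(ev)
  tmpl <- build_template(ef, NULL, k_mad = 3)
  cls <- classify_events(ev, tmpl, denoise_config(), duration = 25)
  expect_true(all(cls$label == "SIGNAL"))

  empty <- classify_events(mea_events(), tmpl, denoise_config())
  expect_identical(nrow(empty), 0L)
})

test_that("metronomic spurious trains are separated from clean spikes", {
  b <- get_benchmark()
  lab <- b$detected
  spur_inj <- b$sim$injected_noise[
    b$sim$injected_noise$noise_category == "SPURIOUS_SPIKE", ]
  spur_ch <- unique(spur_inj$channel)
  spur_events <- lab$channel %in% spur_ch & lab$modality == "SPIKE"
  expect_gte(mean(lab$label[spur_events] == "NOISE"), 0.90)
  clean_spikes <- lab$truth == "SIGNAL" & lab$modality == "SPIKE"
  expect_lte(mean(lab$label[clean_spikes] == "NOISE"), 0.05)
})

test_that("apply_denoising removes nothing from an all-clean recording", {
  cfg <- synth_config(n_rows = 4, n_cols = 4, duration = 8,
                      sampling_rate = 1000,
                      regions = list(synth_region("R", 0, 3, 0, 3,
                                                  lfp_rate = 1,
                                                  prop_speed_um_ms = 1.5)),
                      background_sd_uv = 3, seed = 21)
  out <- generate_clean(cfg)
  ev <- detect_lfp_events(bandpass(out$recording, lfp_filter()))
  rep_ <- apply_denoising(out$recording, ev)
  expect_identical(nrow(rep_$cleaned), nrow(ev))
  expect_identical(rep_$summary$n_noise, 0L)
})

test_that("denoising is idempotent, monotone and leaves voltages untouched", {
  b <- get_benchmark()
  rec <- b$sim$recording
  v_before <- rec$voltages
  rep1 <- b$report
  # cleaned is a subset of the input
  expect_true(all(rep1$cleaned$event_id %in% b$detected$event_id))
  expect_lte(nrow(rep1$cleaned), nrow(b$detected))
  # second application removes nothing
  rep2 <- apply_denoising(rec, rep1$cleaned)
  expect_identical(rep2$summary$n_noise, 0L)
  expect_identical(nrow(rep2$cleaned), nrow(rep1$cleaned))
  # voltages bit-identical before/after
  expect_identical(rec$voltages, v_before)
  # label exclusivity: every event exactly one label, noise categorized
  expect_true(all(rep1$events$label %in% c("SIGNAL", "NOISE")))
  noise <- rep1$events[rep1$events$label == "NOISE", ]
  expect_false(anyNA(noise$noise_category))
  expect_true(all(is.na(rep1$events$noise_category[
    rep1$events$label == "SIGNAL"])))
})
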