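mk_snippet_event <- function(w, sr, modality = "LFP", dur = length(w) / sr) {
  mea_events(1L, 0L, modality, t_on = 0, t_peak = dur / 2, t_off = dur,
             amplitude_uv = max(w) - min(w), waveform = list(w),
             snippet_rate = sr)
}

test_that("event features recover amplitude, frequency and symmetry", {
  sr <- 1000
  tt <- seq(0, 0.5, by = 1 / sr)
  f <- event_features(mk_snippet_event(100 * sin(2 * pi * 30 * tt), sr))
  expect_lt(abs(f$dominant_frequency - 30), 1)
  expect_gt(f$spectral_concentration, 0.9)
  expect_equal(f$amplitude, 200)

  # perfectly antisymmetric biphasic snippet
  bi <- -sin(2 * pi * seq_len(400) / 400) * 60
  f2 <- event_features(mk_snippet_event(bi, sr))
  expect_lt(abs(f2$asymmetry), 1e-8)

  w <- rnorm(120); w <- w / (max(w) - min(w)) * 120
  f3 <- event_features(mk_snippet_event(w, sr))
  expect_equal(f3$amplitude, 120)
})

test_that("asymmetry and dominant frequency ignore DC offsets", {
  sr <- 1000
  tt <- seq_len(500) / sr
  w <- -200 * exp(-(tt - 0.25)^2 / (2 * 0.04^2))
  f0 <- event_features(mk_snippet_event(w, sr))
  f1 <- event_features(mk_snippet_event(w + 50, sr))
  expect_equal(f1$asymmetry, f0$asymmetry, tolerance = 1e-6)
  expect_equal(f1$dominant_frequency, f0$dominant_frequency)
  expect_equal(f1$amplitude, f0$amplitude)
  # a smooth single-lobe deflection is regular; noise bursts are not
  expect_lt(f0$shape_irregularity, 0.2)
  set.seed(4)
  fj <- event_features(mk_snippet_event(rnorm(500) *
                                          (runif(500) < 0.4), sr))
  expect_gt(fj$shape_irregularity, 0.6)
})

test_that("feature computation demands a usable snippet", {
  ev <- mea_events(1L, 0L, "LFP", 0, 0.1, 0.2, 10)
  expect_error(event_features(ev), "snippet")
})

test_that("channel features count rates, bursts and synchrony", {
  tp <- as.vector(outer(c(0, 0.01, 0.02), 0:59, "+"))
  ev <- mea_events(seq_along(tp), rep(0L, length(tp)),
                   rep("SPIKE", length(tp)), t_on = tp, t_peak = tp,
                   t_off = tp + 0.001, amplitude_uv = rep(100, length(tp)))
  cf <- channel_features(ev, 0L, 60, burst_isi_max = 0.1)
  expect_equal(cf$firing_rate, 3)       # 180 events / 60 s
  expect_equal(cf$burst_frequency, 1)   # one 3-spike burst per second

  # 300 events in 60 s -> 5 events/s
  tp2 <- seq(0, 59.9, length.out = 300)
  ev2 <- mea_events(seq_along(tp2), rep(1L, 300), rep("LFP", 300),
                    t_on = tp2, t_peak = tp2, t_off = tp2 + 0.01,
                    amplitude_uv = rep(50, 300))
  expect_equal(channel_features(ev2, 1L, 60)$firing_rate, 5)

  empty <- channel_features(mea_events(), 0L, 60)
  expect_true(all(unlist(empty[-1]) == 0))

  nw <- data.frame(t_start = c(0, 10), t_end = c(5, 12))
  ev3 <- mea_events(1:4, rep(0L, 4), rep("LFP", 4),
                    t_on = c(1, 4, 11, 30), t_peak = c(1, 4, 11, 30),
                    t_off = c(1.1, 4.1, 11.1, 30.1),
                    amplitude_uv = rep(10, 4))
  expect_equal(channel_features(ev3, 0L, 60, nw)$synchrony, 0.75)
})

test_that("network events group co-active channels and merge windows", {
  g <- make_geometry(8, 8, 42)
  shared <- mea_events(1:64, 0:63, rep("LFP", 64), t_on = rep(0.9, 64),
                       t_peak = rep(1, 64), t_off = rep(1.1, 64),
                       amplitude_uv = rep(100, 64))
  ne <- detect_network_events(shared, g, window = 0.05)
  expect_identical(nrow(ne), 1L)
  expect_identical(ne$n_coactive, 64L)

  solo <- mea_events(1:20, rep(0L, 20), rep("LFP", 20),
                     t_on = 1:20, t_peak = 1:20, t_off = 1:20 + 0.01,
                     amplitude_uv = rep(100, 20))
  expect_identical(nrow(detect_network_events(solo, g, min_coactive = 5,
                                              window = 0.05)), 0L)
})

test_that("independent sparse Poisson events produce no network events", {
  g <- make_geometry(8, 8, 42)
  set.seed(17)
  # 20 seeded repetitions; the coincidence probability of >= 20 distinct
  # channels in a 10 ms window at 1 Hz/channel is astronomically small
  for (rep_ in 1:20) {
    times <- sort(runif(64 * 60, 0, 60))
    chans <- sample(0:63, length(times), replace = TRUE)
    ev <- mea_events(seq_along(times), chans, rep("SPIKE", length(times)),
                     t_on = times, t_peak = times, t_off = times + 0.001,
                     amplitude_uv = rep(80, length(times)))
    ne <- detect_network_events(ev, g, min_coactive = 20, window = 0.01)
    expect_identical(nrow(ne), 0L)
  }
})

test_that("template bounds contain clean events and widen with k_mad", {
  out <- spike_fixture(seed = 42, spike_rate = 4)
  fil <- bandpass(out$recording, mua_filter())
  ev <- detect_spikes_ptsd(fil)
  ef <- event_features(ev)
  cf <- do.call(rbind, lapply(unique(ev$channel), function(ch)
    channel_features(ev, ch, 5)))
  t3 <- build_template(ef, cf, k_mad = 3)
  t4 <- build_template(ef, cf, k_mad = 4)
  contained <- function(tmpl) {
    ok <- vapply(names(tmpl$event), function(f)
      mean(ef[[f]] >= tmpl$event[[f]]["low"] &
             ef[[f]] <= tmpl$event[[f]]["high"]), numeric(1))
    mean(ok)
  }
  expect_gte(contained(t3), 0.90)
  expect_gte(contained(t4), contained(t3))
  for (f in names(t3$event)) {
    expect_lte(t4$event[[f]]["low"], t3$event[[f]]["low"])
    expect_gte(t4$event[[f]]["high"], t3$event[[f]]["high"])
  }
})

test_that("clean-recording template contains at least 99% of clean features", {
  b <- get_benchmark()
  clean_ev <- detect_lfp_events(bandpass(b$sim$clean_recording,
                                         lfp_filter()))
  ef <- event_features(clean_ev)
  tmpl <- build_template(ef, NULL, k_mad = 3)
  inside <- rep(TRUE, nrow(ef))
  viol <- rep(0L, nrow(ef))
  for (f in names(tmpl$event))
    viol <- viol + (ef[[f]] < tmpl$event[[f]]["low"] |
                      ef[[f]] > tmpl$event[[f]]["high"])
  # containment in the composite sense used for classification
  expect_gte(mean(viol < 2), 0.99)
})

test_that("degenerate features collapse to a padded point interval", {
  ef <- data.frame(event_id = 1:12, amplitude = rep(100, 12),
                   duration = rep(0.2, 12), dominant_frequency = rep(10, 12),
                   spectral_concentration = rep(0.5, 12),
                   shape_irregularity = rep(0.1, 12),
                   asymmetry = rep(-0.5, 12))
  tmpl <- build_template(ef, NULL)
  b <- tmpl$event$amplitude
  expect_lt(b["high"] - b["low"], 1e-5)
  expect_true(b["low"] <= 100 && 100 <= b["high"])
  expect_false(100.1 <= b["high"])  # a differing value falls outside
  expect_error(build_template(ef[1:5, ], NULL), "insufficient")
})

test_that("templates serialize and reload with bit-identical bounds", {
  ef <- data.frame(event_id = 1:20, amplitude = rnorm(20, 100, 17),
                   duration = runif(20, 0.1, 0.4),
                   dominant_frequency = runif(20, 2, 30),
                   spectral_concentration = runif(20, 0.3, 0.9),
                   shape_irregularity = runif(20),
                   asymmetry = runif(20, -1, 1))
  cf <- data.frame(channel = 0:4, firing_rate = runif(5, 1, 3),
                   burst_frequency = runif(5), synchrony = runif(5),
                   amplitude_cv = runif(5, 0, 0.5), isi_cv = runif(5, 0.5, 2))
  tmpl <- build_template(ef, cf, k_mad = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_template(tmpl, f)
  t2 <- read_template(f)
  for (nm in names(tmpl$event))
    expect_identical(t2$event[[nm]], tmpl$event[[nm]])
  for (nm in names(tmpl$channel))
    expect_identical(t2$channel[[nm]], tmpl$channel[[nm]])
})
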