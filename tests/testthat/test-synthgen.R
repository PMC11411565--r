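test_that("silent configuration produces zero voltages and no events", {
  cfg <- synth_config(n_rows = 2, n_cols = 2, duration = 1,
                      sampling_rate = 1000,
                      regions = list(synth_region("R", 0, 1, 0, 1,
                                                  lfp_rate = 0)),
                      spike_rate = 0, background_sd_uv = 0, seed = 1)
  out <- generate_clean(cfg)
  expect_true(all(out$recording$voltages == 0))
  expect_identical(nrow(out$true_events), 0L)
})

test_that("spike counts follow the configured Poisson rate and match the registry", {
  cfg <- synth_config(n_rows = 2, n_cols = 5, duration = 60,
                      sampling_rate = 5000,
                      regions = list(synth_region("R", 0, 1, 0, 4,
                                                  lfp_rate = 0)),
                      spike_channels = 0:9, spike_rate = 5, burst_prob = 0,
                      background_sd_uv = 1, seed = 9)
  out <- generate_clean(cfg)
  n <- nrow(out$true_events)
  lambda <- 5 * 60 * 10
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  expect_true(all(out$true_events$modality == "SPIKE"))
})

test_that("generation is a pure function of the seed", {
  cfg <- benchmark_config(7L, duration = 3)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$voltages, b$recording$voltages)
  expect_identical(a$true_events, b$true_events)
  expect_identical(a$injected_noise, b$injected_noise)
})

test_that("line injection raises 49-51 Hz band power at least tenfold", {
  set.seed(2)
  rec <- trace_recording(rnorm(10000, 0, 5), 1000)
  out <- inject_noise(rec, noise_spec("LINE", channels = 0L,
                                      amplitude_uv = 20), seed = 5)
  band_power <- function(x, sr) {
    p <- Mod(stats::fft(x))^2
    f <- (0:(length(x) - 1)) / length(x) * sr
    f <- pmin(f, sr - f)
    sum(p[f >= 49 & f <= 51])
  }
  expect_gt(band_power(out$recording$voltages[1, ], 1000) /
              band_power(rec$voltages[1, ], 1000), 10)
})

test_that("zero-amplitude injections leave the recording untouched", {
  rec <- trace_recording(sin(1:5000), 1000)
  for (spec in list(noise_spec("LINE", amplitude_uv = 0),
                    noise_spec("MECHANICAL", amplitude_uv = 0),
                    noise_spec("WHITE", amplitude_uv = 0))) {
    out <- inject_noise(rec, spec, seed = 3)
    expect_identical(out$recording$voltages, rec$voltages)
    expect_identical(nrow(out$registry), 0L)
  }
})

test_that("mechanical transients hit exactly ceiling(fraction x channels)", {
  g <- make_geometry(8, 8, 42)
  rec <- mea_recording(matrix(0, 64, 5000), 1000, g)
  out <- inject_noise(rec, noise_spec("MECHANICAL", channel_fraction = 0.8,
                                      amplitude_uv = 100,
                                      n_transients = 1L), seed = 4)
  expect_identical(length(unique(out$registry$channel)),
                   as.integer(ceiling(0.8 * 64)))
})

test_that("voltage changes are confined to registered noise windows", {
  g <- make_geometry(4, 4, 42)
  set.seed(6)
  rec <- mea_recording(matrix(rnorm(16 * 4000), 16, 4000), 1000, g)
  specs <- list(noise_spec("MECHANICAL", channel_fraction = 0.5,
                           amplitude_uv = 80, n_transients = 2L),
                noise_spec("SPURIOUS_SPIKE", channels = c(1L, 3L),
                           rate_hz = 3, amplitude_uv = 90),
                noise_spec("CALIBRATION", channels = 5L,
                           dc_offset_uv = 200),
                noise_spec("INDUCTIVE", readout_groups = 2L,
                           amplitude_uv = 25))
  for (spec in specs) {
    out <- inject_noise(rec, spec, seed = 8)
    d <- abs(out$recording$voltages - rec$voltages)
    mask <- matrix(FALSE, nrow(d), ncol(d))
    for (i in seq_len(nrow(out$registry))) {
      j0 <- max(1L, floor(out$registry$t_on[i] * 1000))
      j1 <- min(ncol(d), ceiling(out$registry$t_off[i] * 1000) + 1L)
      mask[out$registry$channel[i] + 1L, j0:j1] <- TRUE
    }
    expect_identical(sum(d[!mask] > 1e-9), 0L, info = spec$kind)
  }
})

test_that("unknown noise kinds and bad parameters are rejected", {
  expect_error(noise_spec("GREMLINS"), "unknown noise kind")
  expect_error(noise_spec("LINE", amplitude_uv = -1), "amplitude")
  expect_error(noise_spec("CALIBRATION", dc_offset_uv = 0,
                          saturation_uv = Inf), "CALIBRATION")
})

test_that("spurious spike trains are metronomic by construction", {
  g <- make_geometry(2, 2, 42)
  rec <- mea_recording(matrix(0, 4, 70000), 7000, g)
  out <- inject_noise(rec, noise_spec("SPURIOUS_SPIKE", channels = 0L,
                                      rate_hz = 5, amplitude_uv = 100),
                      seed = 2)
  isi <- diff(sort(out$registry$t_peak))
  expect_lt(stats::sd(isi) / mean(isi), 1e-9)
  expect_equal(mean(isi), 0.2, tolerance = 1e-9)
})
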