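# Shared fixtures. The seeded full benchmark is expensive, so it is
# computed lazily once per test session and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

get_benchmark <- function() {
  cached("bench", run_benchmark(42L, with_baselines = TRUE))
}

get_cat_benchmark <- function() {
  cached("catb", cat_benchmark(get_benchmark()))
}

get_clustering_benchmark <- function() {
  cached("clustb", waveform_clustering_benchmark())
}

# single-channel recording from a bare trace
trace_recording <- function(x, sr) {
  mea_recording(matrix(x, 1L), sr, make_geometry(1L, 1L, 42))
}

# noiseless-ish multichannel recording with Gaussian LFP deflections at
# known times/amplitudes; returns recording + the injected registry
deflection_recording <- function(times, amps, dur = 0.5, sr = 1000,
                                 n_ch = 1L, channel = 0L,
                                 total_s = NULL, noise_sd = 0) {
  if (is.null(total_s)) total_s <- max(times) + dur + 1
  n <- round(total_s * sr)
  v <- matrix(0, n_ch, n)
  if (noise_sd > 0) v <- matrix(rnorm(n_ch * n, 0, noise_sd), n_ch, n)
  sig <- dur / 6
  for (k in seq_along(times)) {
    tt <- (seq_len(round(dur * sr)) - 1L) / sr - dur / 2
    i0 <- round(times[k] * sr) + 1L
    idx <- i0:(i0 + length(tt) - 1L)
    v[channel + 1L, idx] <- v[channel + 1L, idx] - amps[k] * exp(-tt^2 / (2 * sig^2))
  }
  g <- if (n_ch == 1L) make_geometry(1L, 1L, 42)
       else make_geometry(1L, n_ch, 42)
  list(recording = mea_recording(v, sr, g),
       t_peak = times + dur / 2, amps = amps)
}

# small clean spike fixture on a 2x2 grid (see detection oracle tests)
spike_fixture <- function(seed = 7L, spike_rate = 2, sd = 1) {
  cfg <- synth_config(
    n_rows = 2L, n_cols = 2L, duration = 5, sampling_rate = 14000,
    regions = list(synth_region("R", 0L, 1L, 0L, 1L, lfp_rate = 0)),
    spike_channels = 0:3, spike_rate = spike_rate, burst_prob = 0,
    background_sd_uv = sd, seed = seed)
  generate_clean(cfg)
}

# ±tol matching of detected against injected events, per channel
match_rate <- function(detected, truth, tol = 0.001) {
  if (nrow(truth) == 0L) return(list(recall = NA, precision = NA))
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(detected$channel == truth$channel[i] &
          abs(detected$t_peak - truth$t_peak[i]) <= tol), logical(1L))
  ok <- vapply(seq_len(nrow(detected)), function(i)
    any(truth$channel == detected$channel[i] &
          abs(truth$t_peak - detected$t_peak[i]) <= tol), logical(1L))
  list(recall = mean(hit),
       precision = if (nrow(detected)) mean(ok) else NA)
}
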