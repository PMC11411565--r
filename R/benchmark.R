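#' Study conditions of the seeded synthetic benchmark
#'
#' The benchmark emulates, at desk scale, a layered slice on a 12 x 12
#' electrode patch (42 um pitch) sampled at 7.5 kHz for 15 s: two regions
#' ("DG" and "CA1") carry propagating LFP deflections travelling in the +x
#' direction at 1.5 um/ms; the three central rows of CA1 carry bursty
#' 3 Hz spike trains; and all five noise categories are injected on fixed,
#' mutually disjoint channel sets:
#' 50 Hz line pickup on 8 channels, three mechanical transients hitting
#' 80% of the array, inductive coupling on one readout column, metronomic
#' spurious spike trains on 8 otherwise quiet channels, and a +300 uV
#' calibration offset on 6 channels.
#'
#' @param seed master seed.
#' @param duration recording length in seconds.
#' @return a [synth_config()].
#' @export
benchmark_config <- function(seed = 42L, duration = 15) {
  n_rows <- 12L; n_cols <- 12L
  # fixed, disjoint artifact channel sets (0-based; column 3 is inductive)
  line_ch <- c(1L, 14L, 26L, 39L, 52L, 64L, 77L, 90L)
  spur_ch <- c(5L, 8L, 17L, 20L, 29L, 32L, 41L, 44L)   # rows 0-3, no spikes
  calib_ch <- c(2L, 13L, 25L, 38L, 50L, 62L)
  spike_ch <- setdiff(rowcol_to_chan(rep(6:8, each = n_cols),
                                     rep(0:(n_cols - 1L), 3L),
                                     make_geometry(n_rows, n_cols, 42)),
                      c(line_ch, calib_ch))
  synth_config(
    n_rows = n_rows, n_cols = n_cols, pitch = 42,
    duration = duration, sampling_rate = 7500,
    regions = list(
      synth_region("DG", 0L, 5L, 0L, 11L, lfp_rate = 0.5,
                   lfp_amp_uv = c(150, 300), lfp_dur_s = c(0.15, 0.3),
                   prop_speed_um_ms = 1.5, prop_dir_deg = 0),
      synth_region("CA1", 6L, 11L, 0L, 11L, lfp_rate = 0.5,
                   lfp_amp_uv = c(150, 300), lfp_dur_s = c(0.15, 0.3),
                   prop_speed_um_ms = 1.5, prop_dir_deg = 0)),
    spike_channels = spike_ch, spike_rate = 3, burst_prob = 0.2,
    spike_p2p_uv = 120, spike_width_s = 0.0012, spike_amp_cv = 0.15,
    background_sd_uv = 5,
    noise = list(
      noise_spec("LINE", channels = line_ch, amplitude_uv = 40,
                 freq_hz = 50),
      noise_spec("MECHANICAL", channel_fraction = 0.8,
                 amplitude_uv = 150, width_ms = 8, n_transients = 3L),
      noise_spec("INDUCTIVE", readout_groups = 3L, amplitude_uv = 30),
      noise_spec("SPURIOUS_SPIKE", channels = spur_ch, rate_hz = 4,
                 amplitude_uv = 110, spike_width_s = 0.0012),
      noise_spec("CALIBRATION", channels = calib_ch,
                 dc_offset_uv = 300)),
    seed = seed)
}

#' Detect LFP and spike events on a recording
#'
#' Standard two-band detection: 1-100 Hz band + hard thresholding for
#' LFPs, 300-3500 Hz band + PTSD for multi-unit spikes. The MUA high edge
#' is capped just below Nyquist for low sampling rates.
#'
#' @param rec an `mea_recording`.
#' @param params a [detection_params()].
#' @return an `mea_events` with both modalities, ids renumbered.
#' @export
detect_all_events <- function(rec, params = detection_params()) {
  lfp <- detect_lfp_events(bandpass(rec, lfp_filter()), params)
  mua_hi <- min(3500, 0.45 * rec$sampling_rate)
  spk <- detect_spikes_ptsd(bandpass(rec, filter_spec(300, mua_hi)), params)
  out <- ev_bind(lfp, spk)
  if (nrow(out)) out$event_id <- seq_len(nrow(out))
  out
}

#' Match detected events against the simulator's ground truth
#'
#' A detected event is truly noise when it is attributable to an injected
#' noise component on its channel: for sustained contamination (line,
#' inductive, calibration, white) any window overlap counts — those
#' registry windows span the whole contamination period, so genuine LFP
#' waves crossing a contaminated electrode count as noise there too, on
#' both sides of the comparison — while short transients (mechanical,
#' spurious spikes) only claim events whose peak falls inside them. It is
#' truly signal when its peak falls within `tol` of an injected signal
#' event on its channel. Detections matching neither (background false
#' alarms of the detector) are reported as `unmatched` and excluded from
#' the confusion counts.
#'
#' @param detected detected `mea_events`.
#' @param truth a [simulate_recording()] result.
#' @param tol matching tolerance in seconds.
#' @return `detected` with columns `truth` ("NOISE"/"SIGNAL"/"UNMATCHED").
#' @export
match_ground_truth <- function(detected, truth, tol = 0.01) {
  tr <- rep("UNMATCHED", nrow(detected))
  inj <- truth$injected_noise
  tru <- truth$true_events
  transient <- inj$noise_category %in% c("MECHANICAL", "SPURIOUS_SPIKE")
  for (i in seq_len(nrow(detected))) {
    ch <- detected$channel[i]
    jn <- inj$channel == ch & ifelse(
      transient,
      detected$t_peak[i] >= inj$t_on - tol &
        detected$t_peak[i] <= inj$t_off + tol,
      detected$t_on[i] < inj$t_off + tol &
        detected$t_off[i] > inj$t_on - tol)
    if (any(jn)) { tr[i] <- "NOISE"; next }
    js <- tru$channel == ch & tru$modality == detected$modality[i] &
      detected$t_peak[i] >= tru$t_on - tol &
      detected$t_peak[i] <= tru$t_off + tol
    if (any(js)) tr[i] <- "SIGNAL"
  }
  detected$truth <- tr
  detected
}

#' Event-level confusion statistics of a denoising run
#'
#' @param labeled the labelled events from [apply_denoising()] (with a
#'   `truth` column from [match_ground_truth()]).
#' @return list: `precision` and `recall` of noise detection, the
#'   `mislabel_rate` of truly clean events, and the raw counts.
#' @export
confusion_stats <- function(labeled) {
  known <- labeled[labeled$truth != "UNMATCHED", , drop = FALSE]
  tp <- sum(known$label == "NOISE" & known$truth == "NOISE")
  fp <- sum(known$label == "NOISE" & known$truth == "SIGNAL")
  fn <- sum(known$label == "SIGNAL" & known$truth == "NOISE")
  tn <- sum(known$label == "SIGNAL" & known$truth == "SIGNAL")
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       mislabel_rate = if (fp + tn > 0) fp / (fp + tn) else 0,
       tp = tp, fp = fp, fn = fn, tn = tn,
       unmatched = sum(labeled$truth == "UNMATCHED"))
}

rate_bin_for <- function(modality) if (modality == "LFP") 0.05 else 0.01

# per-channel binned event-rate series for one modality
rate_series <- function(events, modality, n_channels, duration) {
  bin <- rate_bin_for(modality)
  n_bins <- floor(duration / bin)
  ev <- events[events$modality == modality, , drop = FALSE]
  m <- matrix(0, n_channels, n_bins)
  if (nrow(ev)) {
    b <- pmin(n_bins, floor(ev$t_peak / bin) + 1L)
    for (i in seq_len(nrow(ev)))
      m[ev$channel[i] + 1L, b[i]] <- m[ev$channel[i] + 1L, b[i]] + 1
  }
  m / bin
}

# The recoverable signal stream: injected events not swallowed by
# sustained contamination (an event on a line/inductive/calibration
# channel is unrecoverable there — no denoiser can certify it).
recoverable_truth <- function(truth) {
  tru <- truth$true_events
  inj <- truth$injected_noise
  sus <- inj[inj$noise_category %in%
               c("LINE", "INDUCTIVE", "CALIBRATION", "GENERIC"), ,
             drop = FALSE]
  if (!nrow(sus) || !nrow(tru)) return(tru)
  drop <- vapply(seq_len(nrow(tru)), function(i)
    any(sus$channel == tru$channel[i] & tru$t_on[i] < sus$t_off &
          tru$t_off[i] > sus$t_on), logical(1L))
  ev_subset(tru, which(!drop))
}

# Ground-truth-referenced per-channel quality of an event stream:
# SNR = (rms of recoverable-truth rate + c) / (rms of residual rate + c),
# with c the one-event quantization floor of the binned series (keeps
# perfectly recovered channels finite); RMS = rms of the residual rate.
# One value per channel that carries truth or detected activity.
rate_channel_quality <- function(events, truth, modality) {
  dur <- truth$config$duration
  n_ch <- truth$config$n_rows * truth$config$n_cols
  bin <- rate_bin_for(modality)
  clean <- rate_series(recoverable_truth(truth), modality, n_ch, dur)
  got <- rate_series(events, modality, n_ch, dur)
  resid <- got - clean
  active <- which(rowSums(got) + rowSums(clean) > 0)
  if (!length(active))
    return(data.frame(channel = integer(), snr = numeric(),
                      rms_err = numeric()))
  cfloor <- (1 / bin) / sqrt(floor(dur / bin))
  s <- apply(clean[active, , drop = FALSE], 1L, rms_noise)
  n <- apply(resid[active, , drop = FALSE], 1L, rms_noise)
  data.frame(channel = active - 1L, snr = (s + cfloor) / (n + cfloor),
             rms_err = n)
}

#' Run the full seeded denoising benchmark
#'
#' Simulates the [benchmark_config()] recording, detects events on the
#' noisy data, runs the denoising engine, scores the labels against the
#' ground truth, and (optionally) compares the denoised event streams with
#' the four classical baselines applied to the voltages before detection.
#'
#' @param seed master seed (default 42).
#' @param duration benchmark duration (s).
#' @param with_baselines also run the FIR/Savitzky-Golay/wavelet/Fourier
#'   comparison (slower).
#' @param config optional [denoise_config()] override.
#' @return list with `sim`, `detected` (truth-matched), `report`,
#'   `confusion`, `metrics` (per method x modality data.frame) and
#'   `snr_dr` (percent, per modality).
#' @export
run_benchmark <- function(seed = 42L, duration = 15,
                          with_baselines = TRUE,
                          config = denoise_config()) {
  sim <- simulate_recording(benchmark_config(seed, duration))
  detected <- detect_all_events(sim$recording)
  report <- apply_denoising(sim$recording, detected, config)
  labeled <- match_ground_truth(report$events, sim)
  conf <- confusion_stats(labeled)

  methods <- list(RAW = detected, DENOISING = report$cleaned)
  if (with_baselines) {
    for (m in c("FIR", "SAVGOL", "WAVELET", "FOURIER")) {
      prm_lfp <- baseline_params(m)   # LFP-range defaults
      prm_spk <- baseline_params(m, fir_cutoff_hz = 3400)
      den_l <- baseline_denoise_recording(sim$recording, prm_lfp)
      den_s <- if (m == "FIR")
        baseline_denoise_recording(sim$recording, prm_spk) else den_l
      lfp <- detect_lfp_events(bandpass(den_l, lfp_filter()))
      mua_hi <- min(3500, 0.45 * sim$recording$sampling_rate)
      spk <- detect_spikes_ptsd(bandpass(den_s, filter_spec(300, mua_hi)))
      methods[[m]] <- ev_bind(lfp, spk)
    }
  }
  quality <- lapply(methods, function(ev) {
    per_mod <- lapply(MODALITIES, rate_channel_quality,
                      events = ev, truth = sim)
    names(per_mod) <- MODALITIES
    per_mod
  })
  metrics <- do.call(rbind, lapply(names(methods), function(m)
    do.call(rbind, lapply(MODALITIES, function(mod) {
      q <- quality[[m]][[mod]]
      data.frame(method = m, modality = mod,
                 median_snr = stats::median(q$snr),
                 rms_err = stats::median(q$rms_err))
    }))))
  # one SNR_DR over the whole array: both modalities' channels pooled
  pooled <- vapply(c("RAW", "DENOISING"), function(m)
    stats::median(c(quality[[m]]$LFP$snr, quality[[m]]$SPIKE$snr)),
    numeric(1L))
  snr_dr_pct <- if (all(pooled > 0) && snr_db(pooled["RAW"]) != 0)
    snr_dr(snr_db(pooled[["RAW"]]), snr_db(pooled[["DENOISING"]]))
  else NA_real_

  list(sim = sim, detected = labeled, report = report, confusion = conf,
       metrics = metrics, quality = quality,
       pooled_snr = pooled, snr_dr = snr_dr_pct)
}

#' Center-of-activity trajectory analysis of a benchmark run
#'
#' Computes, per detected network event of the clean recording, the CAT of
#' the LFP events and its least-squares propagation direction, and the
#' per-bin CAT deviation of the raw and denoised event streams from the
#' clean-data trajectory.
#'
#' Deviations are reported per modality and overall (their mean): the
#' denoised LFP trajectory pays a small footprint cost where contaminated
#' electrodes were removed wholesale, while the spike trajectory gains
#' strongly from the removal of dense spurious/transient events, so the
#' recording-level comparison is the meaningful one.
#'
#' @param bench a [run_benchmark()] result (or a list with `sim`,
#'   `detected`, `report`).
#' @return list: `angle_err_deg` (median absolute direction error vs the
#'   injected propagation direction), `dev` (data.frame of mean CAT
#'   distance from the clean trajectory in um, per modality and stream)
#'   and `dev_raw`, `dev_denoised` (overall).
#' @export
cat_benchmark <- function(bench) {
  sim <- bench$sim
  geom <- sim$recording$geometry
  clean_ev <- detect_lfp_events(bandpass(sim$clean_recording, lfp_filter()))
  netw <- detect_network_events(clean_ev, geom, window = 0.05)
  inj_dir <- sim$config$regions[[1L]]$prop_dir_deg
  angs <- c()
  for (k in seq_len(nrow(netw))) {
    idx <- clean_ev$t_peak >= netw$t_start[k] & clean_ev$t_peak <= netw$t_end[k]
    st <- bin_events(ev_subset(clean_ev, which(idx)), geom, 0.05,
                     t_start = netw$t_start[k], t_end = netw$t_end[k])
    cat_pts <- compute_cat(st, geom)
    if (nrow(cat_pts) >= 3L)
      angs <- c(angs, cat_direction(cat_pts)$angle_deg)
  }
  ang_err <- stats::median(abs((angs - inj_dir + 180) %% 360 - 180))

  dur <- sim$config$duration
  mua_hi <- min(3500, 0.45 * sim$recording$sampling_rate)
  clean_spk <- detect_spikes_ptsd(bandpass(sim$clean_recording,
                                           filter_spec(300, mua_hi)))
  cat_of <- function(ev, mod) {
    sub <- ev[ev$modality == mod, , drop = FALSE]
    compute_cat(bin_events(sub, geom, rate_bin_for(mod),
                           t_start = 0, t_end = dur), geom)
  }
  dev_from <- function(a, b) {
    m <- merge(a, b, by = "t")
    if (!nrow(m)) return(NA_real_)
    mean(sqrt((m$x_um.x - m$x_um.y)^2 + (m$y_um.x - m$y_um.y)^2))
  }
  dev <- do.call(rbind, lapply(MODALITIES, function(mod) {
    cc <- cat_of(if (mod == "LFP") clean_ev else clean_spk, mod)
    data.frame(modality = mod,
               dev_raw = dev_from(cat_of(bench$detected, mod), cc),
               dev_denoised = dev_from(cat_of(bench$report$cleaned, mod),
                                       cc))
  }))
  list(angle_err_deg = ang_err,
       n_network_events = nrow(netw), dev = dev,
       dev_raw = mean(dev$dev_raw), dev_denoised = mean(dev$dev_denoised))
}

#' Three-class waveform mixture with artifacts, for clustering assessment
#'
#' Generates LFP-like snippets of three distinct shape classes
#' (monophasic negative deflection, biphasic wave, slow asymmetric
#' sawtooth-like deflection) plus jagged broadband artifact snippets, as
#' an event table. The engine's template (built from a held-out clean set
#' of the same three classes) separates the artifacts; clustering quality
#' is then compared on raw (all events) versus denoised (SIGNAL-only)
#' sets.
#'
#' @param n_per_class events per signal class.
#' @param n_artifact artifact events.
#' @param seed RNG seed.
#' @return list with `events` (mixture), `reference` (clean events used to
#'   build the template), `truth` (class of each mixture event; 0 =
#'   artifact).
#' @export
waveform_mixture <- function(n_per_class = 60L, n_artifact = 30L,
                             seed = 42L) {
  sr <- 1000
  n <- 400L                  # 0.4 s snippets
  tt <- seq_len(n) / sr
  shapes <- list(
    function(a) -a * exp(-(tt - 0.2)^2 / (2 * 0.03^2)),
    function(a) -a * exp(-(tt - 0.15)^2 / (2 * 0.025^2)) +
      0.7 * a * exp(-(tt - 0.25)^2 / (2 * 0.035^2)),
    function(a) -a * pmax(0, 1 - abs(tt - 0.2) / 0.12) *
      (1 + 0.5 * sin(2 * pi * 12 * tt)))
  gen <- function(n_each, n_art, offset) with_stream(seed, offset, {
    rows <- list()
    for (cl in seq_along(shapes)) {
      for (i in seq_len(n_each)) {
        a <- stats::runif(1, 150, 250)
        w <- shapes[[cl]](a) + stats::rnorm(n, 0, 4)
        rows[[length(rows) + 1L]] <- list(w = w, cls = cl,
                                          amp = max(w) - min(w))
      }
    }
    for (i in seq_len(n_art)) {
      # jagged broadband burst: step discontinuities + heavy noise
      w <- stats::rnorm(n, 0, 60) *
        (stats::runif(n) < 0.3) + 80 * sign(sin(2 * pi * 90 * tt))
      rows[[length(rows) + 1L]] <- list(w = w, cls = 0L,
                                        amp = max(w) - min(w))
    }
    rows
  })
  to_events <- function(rows, t0) {
    k <- seq_along(rows)
    # event window as a detector would report it: the span where the
    # waveform exceeds 10% of its own peak (compact for smooth
    # deflections, the whole snippet for broadband bursts)
    span <- vapply(rows, function(r) {
      above <- which(abs(r$w) > 0.1 * max(abs(r$w)))
      c(min(above), max(above)) / sr
    }, numeric(2L))
    pk <- vapply(rows, function(r) which.max(abs(r$w)) / sr, numeric(1L))
    mea_events(event_id = k, channel = (k - 1L) %% 16L,
               modality = rep("LFP", length(k)),
               t_on = t0 + k + span[1L, ], t_peak = t0 + k + pk,
               t_off = t0 + k + span[2L, ],
               amplitude_uv = vapply(rows, `[[`, 0, "amp"),
               waveform = lapply(rows, `[[`, "w"), snippet_rate = sr)
  }
  mix_rows <- gen(n_per_class, n_artifact, 1L)
  ref_rows <- gen(n_per_class, 0L, 2L)
  list(events = to_events(mix_rows, 0),
       reference = to_events(ref_rows, 1e4),
       truth = vapply(mix_rows, `[[`, 0L, "cls"))
}

#' Clustering-quality comparison on the waveform mixture
#'
#' @param mix a [waveform_mixture()] result.
#' @param config a [denoise_config()].
#' @return list with `sil_raw`, `sil_denoised` (mean silhouettes of the
#'   PCA + mean-shift clusterings) and the labelled mixture table.
#' @export
waveform_clustering_benchmark <- function(mix = waveform_mixture(),
                                          config = denoise_config()) {
  ref_feats <- event_features(mix$reference)
  tmpl <- build_template(ref_feats, NULL, k_mad = config$k_mad)
  tmpl$channel <- NULL
  cls <- classify_events(mix$events, tmpl, config,
                         duration = max(mix$events$t_off))
  denoised <- ev_subset(cls, which(cls$label == "SIGNAL"))
  raw_cl <- cluster_waveforms(mix$events, window_s = 0.4)
  den_cl <- cluster_waveforms(denoised, window_s = 0.4)
  list(sil_raw = raw_cl$mean_silhouette,
       sil_denoised = den_cl$mean_silhouette,
       n_clusters_raw = raw_cl$n_clusters,
       n_clusters_denoised = den_cl$n_clusters,
       labeled = cls)
}
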