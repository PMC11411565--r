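#' Denoising engine configuration
#'
#' Thresholds of the adaptive classification core. The template may be
#' supplied (e.g. reloaded from a previous dataset) or left NULL, in which
#' case [apply_denoising()] adapts one per modality from the recording's
#' own events after the channel/window flaggers have run.
#'
#' @param template optional `noise_template`, or a list
#'   `list(LFP = ..., SPIKE = ...)` of per-modality templates.
#' @param line_hz mains frequency (Hz).
#' @param line_power_ratio_threshold channel flagged as line-contaminated
#'   when (power in `line_hz` +/- 1 Hz) / (power in 1-100 Hz) exceeds this.
#' @param mechanical_k per-channel amplitude threshold (in robust SDs of
#'   the high-passed trace) that counts a channel as hit by a transient.
#' @param mechanical_channel_fraction a window is a mechanical artifact
#'   when more than this fraction of channels are hit inside it.
#' @param mechanical_window window length (s) for the simultaneity test.
#' @param inductive_corr_threshold readout group flagged when the median
#'   pairwise correlation of its channels' event-free LFP-band residuals
#'   exceeds this.
#' @param calibration_offset_threshold |median voltage| above this (uV)
#'   flags a calibration fault.
#' @param saturation_fraction_threshold fraction of samples pinned at a
#'   channel's extreme value above which the channel counts as saturated.
#' @param min_feature_violations an event is noise when at least this many
#'   of its 6 waveform features sit outside template bounds; a channel is
#'   an artifact channel (all its events noise) when at least this many of
#'   its 5 activity features do.
#' @param isi_cv_floor absolute non-physiological regularity criterion: a
#'   channel whose inter-event-interval coefficient of variation falls
#'   below this (with at least `min_channel_events` events) is an artifact
#'   channel regardless of the template — no biological multi-unit train
#'   is metronomic.
#' @param min_channel_events minimum events before the regularity
#'   criterion applies.
#' @param k_mad template interval half-width in MADs.
#' @param burst_isi_max burst definition for the channel features (s).
#' @param network_window_lfp,network_window_spike network-event windows (s).
#' @return a `denoise_config` list.
#' @export
denoise_config <- function(template = NULL, line_hz = 50,
                           line_power_ratio_threshold = 0.3,
                           mechanical_k = 6,
                           mechanical_channel_fraction = 0.5,
                           mechanical_window = 0.01,
                           inductive_corr_threshold = 0.8,
                           calibration_offset_threshold = 100,
                           saturation_fraction_threshold = 0.05,
                           min_feature_violations = 2L,
                           isi_cv_floor = 0.2, min_channel_events = 10L,
                           k_mad = 3,
                           burst_isi_max = 0.1,
                           network_window_lfp = 0.05,
                           network_window_spike = 0.01) {
  stopifnot(line_hz > 0, line_power_ratio_threshold > 0,
            mechanical_k > 0,
            mechanical_channel_fraction > 0,
            mechanical_channel_fraction <= 1,
            mechanical_window > 0, inductive_corr_threshold > 0,
            calibration_offset_threshold > 0,
            saturation_fraction_threshold > 0,
            saturation_fraction_threshold <= 1,
            min_feature_violations >= 1)
  structure(list(template = template, line_hz = line_hz,
                 line_power_ratio_threshold = line_power_ratio_threshold,
                 mechanical_k = mechanical_k,
                 mechanical_channel_fraction = mechanical_channel_fraction,
                 mechanical_window = mechanical_window,
                 inductive_corr_threshold = inductive_corr_threshold,
                 calibration_offset_threshold = calibration_offset_threshold,
                 saturation_fraction_threshold = saturation_fraction_threshold,
                 min_feature_violations = as.integer(min_feature_violations),
                 isi_cv_floor = isi_cv_floor,
                 min_channel_events = as.integer(min_channel_events),
                 k_mad = k_mad, burst_isi_max = burst_isi_max,
                 network_window_lfp = network_window_lfp,
                 network_window_spike = network_window_spike),
            class = "denoise_config")
}

#' Flag channels dominated by mains (line) pickup
#'
#' A channel is flagged when the periodogram power within +/- 1 Hz of the
#' line frequency, as a fraction of the total 1-100 Hz power, exceeds the
#' configured threshold. Channels with zero total band power are never
#' flagged.
#'
#' @param rec an `mea_recording` of at least 1 s.
#' @param config a [denoise_config()].
#' @return logical vector, one flag per channel.
#' @export
flag_line_noise <- function(rec, config = denoise_config()) {
  if (rec_duration(rec) < 1) stop("line-noise flagging needs >= 1 s of data")
  n <- ncol(rec$voltages)
  sr <- rec$sampling_rate
  freq <- (0:(n - 1L)) / n * sr
  band <- freq >= 1 & freq <= 100
  line <- abs(freq - config$line_hz) <= 1
  p <- Mod(stats::mvfft(t(rec$voltages)))^2
  tot <- colSums(p[band, , drop = FALSE])
  inl <- colSums(p[band & line, , drop = FALSE])
  ifelse(tot > 0, inl / tot > config$line_power_ratio_threshold, FALSE)
}

#' Flag mechanical (perfusion-glitch) artifact windows
#'
#' Mechanical transients are broadband and hit most of the array at once.
#' The recording is high-passed (300 Hz to just below Nyquist) to suppress
#' slow LFP waves, each channel gets a robust amplitude threshold
#' (`mechanical_k` x its own noise SD), and any `mechanical_window` bin in
#' which more than `mechanical_channel_fraction` of channels are
#' suprathreshold is flagged. Adjacent flagged bins merge into one window.
#'
#' @param rec an `mea_recording` (raw, unfiltered).
#' @param config a [denoise_config()].
#' @return data.frame of windows `t_start`, `t_end`, `n_channels_hit`.
#' @export
flag_mechanical <- function(rec, config = denoise_config()) {
  sr <- rec$sampling_rate
  hp <- bandpass(rec, filter_spec(300, min(3500, 0.45 * sr)))
  v <- hp$voltages
  thr <- apply(v, 1L, estimate_noise_sd) * config$mechanical_k
  hit <- sweep(abs(v), 1L, thr, ">")
  # per bin, fraction of channels with any suprathreshold sample
  binw <- round(config$mechanical_window * sr)
  nbins <- ceiling(ncol(v) / binw)
  frac <- numeric(nbins); nhit <- integer(nbins)
  for (b in seq_len(nbins)) {
    j0 <- (b - 1L) * binw + 1L; j1 <- min(ncol(v), b * binw)
    chans_hit <- rowSums(hit[, j0:j1, drop = FALSE]) > 0L
    frac[b] <- mean(chans_hit); nhit[b] <- sum(chans_hit)
  }
  flagged <- frac > config$mechanical_channel_fraction
  if (!any(flagged))
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      n_channels_hit = integer()))
  r <- rle(flagged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- data.frame(
    t_start = rec$t0 + (starts[r$values] - 1L) * config$mechanical_window,
    t_end = rec$t0 + ends[r$values] * config$mechanical_window)
  out$n_channels_hit <- vapply(seq_len(nrow(out)), function(k)
    max(nhit[starts[r$values][k]:ends[r$values][k]]), integer(1L))
  out
}

#' Flag readout groups carrying inductive-coupling noise
#'
#' Inductive pickup in the chip wiring adds one shared waveform to every
#' channel of a readout group before amplification, so the group's
#' channels stay correlated even after each channel's own detected events
#' are masked out. A group of >= 2 channels is flagged when the median
#' pairwise correlation of its event-free residuals exceeds the threshold;
#' single-channel groups are skipped. Residuals are taken in the 5-100 Hz
#' sub-band: slow deflections leave sub-5 Hz baseline-recovery tails well
#' beyond their detected windows, which would otherwise masquerade as (or
#' dilute) shared coupling, while inductive pickup is broadband across the
#' LFP range.
#'
#' @param rec an `mea_recording`.
#' @param events detected events on `rec` (their windows are masked out
#'   before correlating); may be empty.
#' @param config a [denoise_config()].
#' @return data.frame with `readout_group`, `n_channels`, `median_corr`,
#'   `flagged`.
#' @export
flag_inductive <- function(rec, events = mea_events(),
                           config = denoise_config()) {
  sr <- rec$sampling_rate
  lf <- bandpass(rec, filter_spec(5, 100))
  stride <- max(1L, floor(sr / 1000))   # 1 kHz is ample for this band
  v <- lf$voltages[, seq(1L, ncol(lf$voltages), by = stride), drop = FALSE]
  srd <- sr / stride
  nd <- ncol(v)
  groups <- sort(unique(rec$geometry$readout_group))
  out <- lapply(groups, function(g) {
    ch <- which(rec$geometry$readout_group == g)
    if (length(ch) < 2L)
      return(data.frame(readout_group = g, n_channels = length(ch),
                        median_corr = NA_real_, flagged = FALSE))
    # union time mask over the group's detected events, with a margin
    # covering the sub-threshold tails of slow deflections, so genuine
    # shared activity does not masquerade as coupling
    keep <- rep(TRUE, nd)
    gev <- which(events$channel %in% (ch - 1L))
    for (i in gev) {
      margin <- 0.1 + 0.5 * (events$t_off[i] - events$t_on[i])
      j0 <- max(1L, floor((events$t_on[i] - rec$t0 - margin) * srd) + 1L)
      j1 <- min(nd, ceiling((events$t_off[i] - rec$t0 + margin) * srd))
      if (j0 <= j1) keep[j0:j1] <- FALSE
    }
    if (sum(keep) < 50L)
      return(data.frame(readout_group = g, n_channels = length(ch),
                        median_corr = NA_real_, flagged = FALSE))
    cm <- suppressWarnings(stats::cor(t(v[ch, keep, drop = FALSE])))
    med <- stats::median(cm[upper.tri(cm)], na.rm = TRUE)
    data.frame(readout_group = g, n_channels = length(ch),
               median_corr = med,
               flagged = !is.na(med) && med > config$inductive_corr_threshold)
  })
  do.call(rbind, out)
}

#' Flag channels with chip calibration faults
#'
#' The auto-zeroing circuit normally holds each electrode near 0 V DC; a
#' fault shows up as a large baseline offset or as samples pinned at the
#' channel's extreme (saturated) values. A channel is flagged when
#' `|median voltage|` exceeds `calibration_offset_threshold` or the
#' fraction of samples at its extreme values exceeds
#' `saturation_fraction_threshold`.
#'
#' @param rec an `mea_recording`.
#' @param config a [denoise_config()].
#' @return logical vector, one flag per channel.
#' @export
flag_calibration <- function(rec, config = denoise_config()) {
  apply(rec$voltages, 1L, function(v) {
    if (abs(stats::median(v)) > config$calibration_offset_threshold)
      return(TRUE)
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(FALSE)
    sat <- mean(v == rng[1L]) + mean(v == rng[2L])
    sat > config$saturation_fraction_threshold
  })
}

#' Classify events against a feature template
#'
#' Two composite rules decide the label:
#' \itemize{
#'   \item event rule — an event with at least `min_feature_violations` of
#'     its 6 waveform features outside the template bounds is noise;
#'   \item channel rule — a channel with at least `min_feature_violations`
#'     of its 5 activity features outside bounds, or with a metronomic
#'     event train (ISI coefficient of variation below `isi_cv_floor` —
#'     non-physiological regularity), is an artifact channel and all its
#'     events are noise. The rule only applies to channels with at least
#'     `min_channel_events` events: activity statistics estimated from a
#'     handful of events are noise themselves.
#' }
#' Noise from either rule is categorized SPURIOUS_SPIKE for spike events
#' and GENERIC otherwise; everything else is SIGNAL. Events of different
#' modalities must be classified against a template built from the same
#' modality.
#'
#' @param events an `mea_events` with waveform snippets.
#' @param template a `noise_template` (see [build_template()]).
#' @param config a [denoise_config()].
#' @param duration recording duration (s) for the channel features.
#' @param network_events optional network-event windows.
#' @return `events` with `label`/`noise_category` filled, plus a
#'   `violations` column.
#' @export
classify_events <- function(events, template, config = denoise_config(),
                            duration = NULL, network_events = NULL) {
  if (nrow(events) == 0L) {
    events$violations <- integer(0)
    return(events)
  }
  if (is.null(duration)) duration <- max(events$t_off)
  ef <- event_features(events)
  for (f in EVENT_FEATURE_NAMES)
    if (is.null(template$event[[f]]))
      stop(sprintf("template lacks event feature '%s'", f))
  viol_ev <- rowSums(vapply(EVENT_FEATURE_NAMES, function(f) {
    b <- template$event[[f]]
    ef[[f]] < b["low"] | ef[[f]] > b["high"]
  }, logical(nrow(ef))))
  ch_bad <- rep(FALSE, nrow(events))
  viol_ch <- rep(0L, nrow(events))
  if (!is.null(template$channel)) {
    cf <- do.call(rbind, lapply(unique(events$channel), function(ch)
      channel_features(events, ch, duration, network_events,
                       config$burst_isi_max)))
    vch <- rowSums(vapply(CHANNEL_FEATURE_NAMES, function(f) {
      b <- template$channel[[f]]
      cf[[f]] < b["low"] | cf[[f]] > b["high"]
    }, logical(nrow(cf))))
    n_ev_ch <- vapply(cf$channel, function(ch)
      sum(events$channel == ch), integer(1L))
    # channel statistics are only evidence when estimated from enough
    # events; CV estimates from a handful of events are noise themselves
    bad <- n_ev_ch >= config$min_channel_events &
      (vch >= config$min_feature_violations |
         cf$isi_cv < config$isi_cv_floor)
    m <- match(events$channel, cf$channel)
    viol_ch <- vch[m]
    ch_bad <- bad[m]
  }
  viol <- viol_ev + viol_ch
  noisy <- viol_ev >= config$min_feature_violations | ch_bad
  events$label <- ifelse(noisy, "NOISE", "SIGNAL")
  events$noise_category <- ifelse(
    noisy, ifelse(events$modality == "SPIKE", "SPURIOUS_SPIKE", "GENERIC"),
    NA_character_)
  events$violations <- as.integer(viol)
  events
}

#' Run the full denoising engine on detected events
#'
#' Runs the four channel/window flaggers (mechanical, line, inductive,
#' calibration — in that precedence order when several apply to one event)
#' and then the template classifier on the surviving events, per modality.
#' When no template is supplied, one is adapted per modality from the
#' recording's own post-flagging events and the classification is iterated
#' to a fixed point, which makes the whole operation idempotent. Raw
#' voltages are never modified: denoising labels events and channels, and
#' the cleaned table is always a subset of the input.
#'
#' @param rec the raw `mea_recording` the events were detected on.
#' @param events detected `mea_events` (LFP and/or SPIKE).
#' @param config a [denoise_config()].
#' @return a `denoise_report`: list with `events` (labelled), `cleaned`
#'   (SIGNAL rows only), `flagged_channels` (per-category 0-based channel
#'   sets), `mechanical_windows`, `inductive`, `templates` (per modality)
#'   and `summary` (per-category counts).
#' @export
apply_denoising <- function(rec, events, config = denoise_config()) {
  validate_recording(rec)
  validate_events(events)
  dur <- rec_duration(rec)
  labels <- rep(NA_character_, nrow(events))
  categ <- rep(NA_character_, nrow(events))

  mech <- flag_mechanical(rec, config)
  line <- flag_line_noise(rec, config)
  indt <- flag_inductive(rec, events, config)
  calib <- flag_calibration(rec, config)
  ind_ch <- which(rec$geometry$readout_group %in%
                    indt$readout_group[indt$flagged]) - 1L

  if (nrow(events)) {
    # a short transient explains an event only when the event peaks in it
    in_mech <- rep(FALSE, nrow(events))
    if (nrow(mech))
      for (k in seq_len(nrow(mech)))
        in_mech <- in_mech | (events$t_peak >= mech$t_start[k] - config$mechanical_window &
                              events$t_peak <= mech$t_end[k] + config$mechanical_window)
    set_cat <- function(mask, cat) {
      new <- mask & is.na(categ)
      labels[new] <<- "NOISE"; categ[new] <<- cat
    }
    set_cat(in_mech, "MECHANICAL")
    set_cat(line[events$channel + 1L], "LINE")
    set_cat(events$channel %in% ind_ch, "INDUCTIVE")
    set_cat(calib[events$channel + 1L], "CALIBRATION")
  }

  # template classification of the unflagged remainder, per modality,
  # iterated to a fixed point so reapplication changes nothing
  templates <- list()
  pending <- which(is.na(labels))
  for (mod in unique(events$modality[pending])) {
    idx <- pending[events$modality[pending] == mod]
    netw <- if (mod == "LFP") config$network_window_lfp
            else config$network_window_spike
    given <- config$template
    if (inherits(given, "noise_template")) tmpl <- given
    else if (!is.null(given) && !is.null(given[[mod]])) tmpl <- given[[mod]]
    else tmpl <- NULL
    active <- idx
    for (pass in seq_len(if (is.null(tmpl)) 5L else 1L)) {
      sub <- ev_subset(events, active)
      if (is.null(config$template)) {
        if (length(active) < 10L) break
        ne <- detect_network_events(sub, rec$geometry, window = netw)
        ef <- event_features(sub)
        cf <- do.call(rbind, lapply(unique(sub$channel), function(ch)
          channel_features(sub, ch, dur, ne, config$burst_isi_max)))
        tmpl <- build_template(ef, cf, ne, k_mad = config$k_mad)
      }
      ne <- detect_network_events(sub, rec$geometry, window = netw)
      cls <- classify_events(sub, tmpl, config, dur, ne)
      bad <- which(cls$label == "NOISE")
      if (length(bad)) {
        labels[active[bad]] <- "NOISE"
        categ[active[bad]] <- cls$noise_category[bad]
        active <- active[-bad]
      }
      if (!is.null(config$template) || !length(bad)) break
      tmpl <- NULL     # re-adapt on the reduced set
    }
    if (length(active)) labels[active] <- "SIGNAL"
    templates[[mod]] <- tmpl
  }
  labels[is.na(labels)] <- "SIGNAL"

  out <- events
  out$label <- labels
  out$noise_category <- categ
  cleaned <- ev_subset(out, which(out$label == "SIGNAL"))
  summary <- table(factor(categ[labels == "NOISE"],
                          levels = NOISE_CATEGORIES))
  structure(list(
    events = out, cleaned = cleaned,
    flagged_channels = list(
      LINE = which(line) - 1L, INDUCTIVE = ind_ch,
      CALIBRATION = which(calib) - 1L),
    mechanical_windows = mech, inductive = indt,
    templates = templates,
    summary = list(n_events = nrow(events),
                   n_signal = sum(labels == "SIGNAL"),
                   n_noise = sum(labels == "NOISE"),
                   by_category = as.list(summary))),
    class = "denoise_report")
}

#' @export
print.denoise_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("denoise_report: %d events -> %d signal, %d noise\n",
              s$n_events, s$n_signal, s$n_noise))
  for (k in names(s$by_category))
    if (s$by_category[[k]] > 0)
      cat(sprintf("  %-15s %d\n", k, s$by_category[[k]]))
  invisible(x)
}
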