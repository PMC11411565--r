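#' Band-pass filter specification
#'
#' @param low_hz,high_hz band edges in Hz, `0 <= low_hz < high_hz`.
#' @param order Butterworth order applied at each band edge (default 4).
#' @return a `filter_spec` list.
#' @seealso [lfp_filter()] and [mua_filter()] for the standard bands.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4L) {
  if (low_hz < 0 || high_hz <= low_hz)
    stop("need 0 <= low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 order = as.integer(order)), class = "filter_spec")
}

#' @rdname filter_spec
#' @details `lfp_filter()` is the 1-100 Hz LFP band (the stated 1 Hz lower
#'   edge makes it a band-pass); `mua_filter()` is the 300-3500 Hz
#'   multi-unit band.
#' @export
lfp_filter <- function(order = 4L) filter_spec(1, 100, order)

#' @rdname filter_spec
#' @export
mua_filter <- function(order = 4L) filter_spec(300, 3500, order)

#' Zero-phase band-pass filtering of a recording
#'
#' Filters every channel with an exactly zero-phase frequency-domain filter
#' whose magnitude is the squared `order`-th Butterworth response at each
#' band edge (the magnitude a forward-backward time-domain Butterworth
#' would have). Zero phase keeps event times unshifted, which the
#' center-of-activity analyses rely on; applying the response in the
#' frequency domain is unconditionally stable even for band edges that are
#' a tiny fraction of the sampling rate (1 Hz at 14 kHz), where
#' transfer-function filtering breaks down numerically.
#'
#' @param rec an `mea_recording`.
#' @param spec a [filter_spec()]; `high_hz` must be below Nyquist.
#' @return filtered `mea_recording` of the same shape.
#' @export
bandpass <- function(rec, spec) {
  validate_recording(rec)
  sr <- rec$sampling_rate
  if (spec$high_hz >= sr / 2)
    stop(sprintf("high_hz = %g exceeds Nyquist (%g Hz)", spec$high_hz,
                 sr / 2))
  n <- ncol(rec$voltages)
  f <- (0:(n - 1L)) / n * sr
  f <- pmin(f, sr - f)                       # two-sided spectrum
  h2 <- rep(1, n)
  if (spec$low_hz > 0) {
    r <- (f / spec$low_hz)^(2L * spec$order)
    h2 <- h2 * r / (1 + r)                   # |H_hp|^2
  }
  h2 <- h2 / (1 + (f / spec$high_hz)^(2L * spec$order))  # * |H_lp|^2
  vf <- t(stats::mvfft(t(rec$voltages)))
  out <- Re(t(stats::mvfft(t(vf * rep(h2, each = nrow(vf))),
                           inverse = TRUE))) / n
  mea_recording(out, sr, rec$geometry, t0 = rec$t0, quantize = FALSE)
}

#' Robust per-channel noise SD estimate
#'
#' `median(|x - median(x)|) / 0.6745`: the MAD-based estimate of the
#' Gaussian noise SD, resistant to contamination by the very events being
#' detected.
#'
#' @param trace numeric voltage vector, at least 100 samples.
#' @return estimated SD in the trace's units.
#' @export
estimate_noise_sd <- function(trace) {
  if (length(trace) < 100L)
    stop("estimate_noise_sd needs at least 100 samples")
  stats::median(abs(trace - stats::median(trace))) / 0.6745
}

#' Detection parameters for LFP and spike events
#'
#' @param lfp_k LFP hard threshold in multiples of the channel noise SD.
#' @param lfp_threshold_uv optional absolute LFP threshold (uV) overriding
#'   `lfp_k * SD`.
#' @param lfp_min_duration,lfp_max_duration event duration bounds (s).
#' @param lfp_refractory events starting within this of the previous
#'   event's end are merged (s).
#' @param spike_k PTSD differential threshold in multiples of the noise SD
#'   (on the peak-to-peak excursion).
#' @param spike_plp peak lifetime period (s): the window within which the
#'   two opposite-sign extrema of a spike must occur.
#' @param spike_refractory minimum separation of detections (s); the larger
#'   excursion wins.
#' @return a `detection_params` list.
#' @export
detection_params <- function(lfp_k = 5, lfp_threshold_uv = NULL,
                             lfp_min_duration = 0.02, lfp_max_duration = 2,
                             lfp_refractory = 0.1,
                             spike_k = 8, spike_plp = 0.002,
                             spike_refractory = 0.001) {
  stopifnot(lfp_k > 0, lfp_min_duration > 0,
            lfp_min_duration < lfp_max_duration, lfp_refractory > 0,
            spike_k > 0, spike_plp > 0, spike_refractory > 0)
  structure(list(lfp_k = lfp_k, lfp_threshold_uv = lfp_threshold_uv,
                 lfp_min_duration = lfp_min_duration,
                 lfp_max_duration = lfp_max_duration,
                 lfp_refractory = lfp_refractory, spike_k = spike_k,
                 spike_plp = spike_plp,
                 spike_refractory = spike_refractory),
            class = "detection_params")
}

# snippet around [i0, i1] with a margin, clipped to the trace
extract_snippet <- function(trace, i0, i1, margin) {
  a <- max(1L, i0 - margin); b <- min(length(trace), i1 + margin)
  trace[a:b]
}

#' Hard-threshold LFP event detection
#'
#' Per channel, marks events where `|v|` exceeds the threshold (`lfp_k`
#' times the channel's robust noise SD, or the absolute override). Event
#' boundaries sit at the threshold crossings; events whose onset falls
#' within the refractory period of the previous event's end are merged;
#' events shorter than `lfp_min_duration` or longer than `lfp_max_duration`
#' are discarded. Both polarities are detected. Amplitude is the
#' peak-to-peak voltage inside `[t_on, t_off)`.
#'
#' @param rec_filtered an LFP-band filtered `mea_recording` (see
#'   [bandpass()]; the detector trusts the caller on this).
#' @param params a [detection_params()].
#' @return an `mea_events` table with waveform snippets (event window plus
#'   a 50% margin each side).
#' @export
detect_lfp_events <- function(rec_filtered, params = detection_params()) {
  sr <- rec_filtered$sampling_rate
  rows <- list()
  for (ch in seq_len(nrow(rec_filtered$voltages)) - 1L) {
    v <- rec_filtered$voltages[ch + 1L, ]
    thr <- if (!is.null(params$lfp_threshold_uv)) params$lfp_threshold_uv
           else params$lfp_k * estimate_noise_sd(v)
    if (thr <= 0) next
    r <- rle(abs(v) > thr)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i0 <- starts[r$values]; i1 <- ends[r$values]
    # merge runs separated by less than the refractory period
    gap_s <- (i0[-1L] - i1[-length(i1)] - 1L) / sr
    grp <- cumsum(c(0L, gap_s >= params$lfp_refractory))
    i0 <- tapply(i0, grp, min); i1 <- tapply(i1, grp, max)
    dur <- (i1 - i0 + 1L) / sr
    keep <- dur >= params$lfp_min_duration & dur <= params$lfp_max_duration
    for (k in which(keep)) {
      seg <- v[i0[k]:i1[k]]
      ipk <- i0[k] + which.max(abs(seg)) - 1L
      margin <- ceiling((i1[k] - i0[k] + 1L) / 2)
      rows[[length(rows) + 1L]] <- list(
        channel = ch, t_on = (i0[k] - 1L) / sr, t_peak = (ipk - 1L) / sr,
        t_off = i1[k] / sr, amplitude_uv = max(seg) - min(seg),
        waveform = extract_snippet(v, i0[k], i1[k], margin))
    }
  }
  detection_rows_to_events(rows, "LFP", sr, rec_filtered$t0)
}

#' Precise timing spike detection (PTSD)
#'
#' Per channel, a spike is declared when the peak-to-peak excursion between
#' a local minimum and the opposite-sign extremum within one peak lifetime
#' period exceeds `spike_k` times the channel's robust noise SD
#' (differential threshold). Spike time is the larger-magnitude extremum;
#' detections closer than the refractory period are suppressed keeping the
#' larger excursion.
#'
#' @param rec_filtered an MUA-band filtered `mea_recording`.
#' @param params a [detection_params()].
#' @return an `mea_events` table; snippets span one peak lifetime period
#'   either side of the spike peak.
#' @export
detect_spikes_ptsd <- function(rec_filtered, params = detection_params()) {
  sr <- rec_filtered$sampling_rate
  plp <- round(params$spike_plp * sr)
  if (plp < 2L) stop("peak lifetime period shorter than 2 samples")
  refr <- params$spike_refractory * sr
  rows <- list()
  for (ch in seq_len(nrow(rec_filtered$voltages)) - 1L) {
    v <- rec_filtered$voltages[ch + 1L, ]
    thr <- params$spike_k * estimate_noise_sd(v)
    cand <- .ptsd_candidates(v, thr, plp)
    if (nrow(cand) == 0L) next
    cand <- cand[order(cand[, "peak"]), , drop = FALSE]
    # refractory suppression, larger excursion wins
    keep <- rep(TRUE, nrow(cand))
    last <- 1L
    for (k in seq_len(nrow(cand))[-1L]) {
      if (cand[k, "peak"] - cand[last, "peak"] < refr) {
        if (cand[k, "p2p"] > cand[last, "p2p"]) {
          keep[last] <- FALSE; last <- k
        } else keep[k] <- FALSE
      } else last <- k
    }
    cand <- cand[keep, , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      ipk <- cand[k, "peak"]
      ia <- min(cand[k, "imin"], cand[k, "imax"])
      ib <- max(cand[k, "imin"], cand[k, "imax"])
      rows[[length(rows) + 1L]] <- list(
        channel = ch, t_on = (ia - 1L) / sr, t_peak = (ipk - 1L) / sr,
        t_off = ib / sr, amplitude_uv = cand[k, "p2p"],
        waveform = v[max(1L, ipk - plp):min(length(v), ipk + plp)])
    }
  }
  detection_rows_to_events(rows, "SPIKE", sr, rec_filtered$t0)
}

detection_rows_to_events <- function(rows, modality, sr, t0) {
  if (!length(rows)) return(mea_events())
  mea_events(
    event_id = seq_along(rows),
    channel = vapply(rows, `[[`, 0L, "channel"),
    modality = rep(modality, length(rows)),
    t_on = t0 + vapply(rows, `[[`, 0, "t_on"),
    t_peak = t0 + vapply(rows, `[[`, 0, "t_peak"),
    t_off = t0 + vapply(rows, `[[`, 0, "t_off"),
    amplitude_uv = vapply(rows, `[[`, 0, "amplitude_uv"),
    waveform = lapply(rows, `[[`, "waveform"),
    snippet_rate = sr)
}
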