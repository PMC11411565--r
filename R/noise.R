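NOISE_KINDS <- c("LINE", "MECHANICAL", "INDUCTIVE", "SPURIOUS_SPIKE",
                 "CALIBRATION", "WHITE")

#' Specification of one noise injection
#'
#' Describes one instance of the five-category noise taxonomy the denoising
#' engine must separate, plus plain extra white noise:
#' \describe{
#'   \item{LINE}{mains pickup: a sinusoid (default 50 Hz) of the given
#'     amplitude added to the selected channels over the time window.}
#'   \item{MECHANICAL}{perfusion-glitch transients: near-simultaneous
#'     broadband damped oscillations hitting a large channel fraction.}
#'   \item{INDUCTIVE}{one shared band-limited waveform added identically to
#'     every channel of the target readout group(s) (coupling in the chip
#'     wiring before amplification).}
#'   \item{SPURIOUS_SPIKE}{spike-shaped transients with non-physiological
#'     regularity: metronomic inter-spike intervals and zero amplitude
#'     variability.}
#'   \item{CALIBRATION}{auto-zeroing faults: a DC baseline offset and/or
#'     hard clipping at a saturation level on the selected channels.}
#'   \item{WHITE}{additional Gaussian noise (for SNR sweeps).}
#' }
#'
#' @param kind one of `"LINE"`, `"MECHANICAL"`, `"INDUCTIVE"`,
#'   `"SPURIOUS_SPIKE"`, `"CALIBRATION"`, `"WHITE"`.
#' @param channels 0-based channel indices, or NULL to use
#'   `channel_fraction`.
#' @param channel_fraction fraction of all channels to affect (selected
#'   deterministically from the injection seed). MECHANICAL affects exactly
#'   `ceiling(fraction * n_channels)` channels.
#' @param window length-2 time window in seconds (NULL = whole recording).
#' @param amplitude_uv kind-specific amplitude: LINE sine amplitude,
#'   MECHANICAL transient peak, INDUCTIVE shared-waveform SD,
#'   SPURIOUS_SPIKE template peak-to-peak, WHITE SD.
#' @param freq_hz LINE frequency (default 50).
#' @param width_ms MECHANICAL transient width.
#' @param n_transients MECHANICAL transient count.
#' @param readout_groups INDUCTIVE target group ids (from the geometry's
#'   `readout_group`).
#' @param rate_hz SPURIOUS_SPIKE train rate (metronomic).
#' @param spike_width_s SPURIOUS_SPIKE template width.
#' @param dc_offset_uv CALIBRATION baseline offset (0 for none).
#' @param saturation_uv CALIBRATION clipping level (Inf for none).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(kind, channels = NULL, channel_fraction = NULL,
                       window = NULL, amplitude_uv = 50, freq_hz = 50,
                       width_ms = 20, n_transients = 3L,
                       readout_groups = 0L, rate_hz = 5,
                       spike_width_s = 0.0012, dc_offset_uv = 300,
                       saturation_uv = Inf) {
  if (!kind %in% NOISE_KINDS)
    stop(sprintf("unknown noise kind '%s'", kind))
  if (amplitude_uv < 0) stop("amplitude_uv must be >= 0")
  if (kind == "LINE" && freq_hz <= 0) stop("freq_hz must be > 0")
  if (kind == "CALIBRATION" && dc_offset_uv == 0 && !is.finite(saturation_uv))
    stop("CALIBRATION needs a dc_offset_uv or a finite saturation_uv")
  structure(list(kind = kind, channels = channels,
                 channel_fraction = channel_fraction, window = window,
                 amplitude_uv = amplitude_uv, freq_hz = freq_hz,
                 width_ms = width_ms, n_transients = as.integer(n_transients),
                 readout_groups = as.integer(readout_groups),
                 rate_hz = rate_hz, spike_width_s = spike_width_s,
                 dc_offset_uv = dc_offset_uv, saturation_uv = saturation_uv),
            class = "noise_spec")
}

resolve_noise_channels <- function(spec, rec, seed) {
  n_ch <- n_channels(rec)
  if (spec$kind == "INDUCTIVE")
    return(which(rec$geometry$readout_group %in% spec$readout_groups) - 1L)
  if (!is.null(spec$channels)) {
    if (any(spec$channels < 0 | spec$channels >= n_ch))
      stop("noise spec: channel index out of range")
    return(as.integer(spec$channels))
  }
  if (!is.null(spec$channel_fraction)) {
    k <- ceiling(spec$channel_fraction * n_ch)
    return(with_stream(seed, 77L, sort(sample.int(n_ch, k) - 1L)))
  }
  seq_len(n_ch) - 1L
}

#' Inject one noise component into a recording
#'
#' Returns a new recording (the input is never modified) plus a registry of
#' every injected noise window so ground-truth masks can be reconstructed
#' exactly: voltages differ from the input only on registered
#' channel/window combinations.
#'
#' @param rec an `mea_recording`.
#' @param spec a [noise_spec()].
#' @param seed integer seed for this injection's random draws.
#' @return list with `recording` and `registry` (an `mea_events` with
#'   `label = "NOISE"` and `noise_category` set; WHITE injections register
#'   the affected window but carry category `"GENERIC"`).
#' @export
inject_noise <- function(rec, spec, seed = 1L) {
  validate_recording(rec)
  sr <- rec$sampling_rate
  n_s <- ncol(rec$voltages)
  dur <- n_s / sr
  win <- if (is.null(spec$window)) c(0, dur) else spec$window
  i0 <- max(1L, floor(win[1L] * sr) + 1L)
  i1 <- min(n_s, ceiling(win[2L] * sr))
  chans <- resolve_noise_channels(spec, rec, seed)
  v <- rec$voltages
  reg <- list()
  add_reg <- function(ch, t_on, t_peak, t_off, amp, category = spec$kind,
                      modality = "LFP") {
    reg[[length(reg) + 1L]] <<- data.frame(
      channel = ch, modality = modality, t_on = t_on, t_peak = t_peak,
      t_off = t_off, amplitude_uv = amp, noise_category = category)
  }

  if (spec$amplitude_uv > 0 || spec$kind == "CALIBRATION") {
    switch(spec$kind,
      LINE = {
        phase <- with_stream(seed, 1L, stats::runif(1, 0, 2 * pi))
        tt <- (i0:i1 - 1L) / sr
        wave <- spec$amplitude_uv * sin(2 * pi * spec$freq_hz * tt + phase)
        for (ch in chans) {
          v[ch + 1L, i0:i1] <- v[ch + 1L, i0:i1] + wave
          add_reg(ch, win[1L], mean(win), win[2L], 2 * spec$amplitude_uv)
        }
      },
      MECHANICAL = {
        w_s <- spec$width_ms / 1000
        centers <- with_stream(seed, 2L,
          sort(stats::runif(spec$n_transients, win[1L] + w_s,
                            win[2L] - w_s)))
        jit <- with_stream(seed, 3L,
          matrix(stats::runif(length(chans) * length(centers),
                              0, 0.0005), length(chans)))
        n_w <- round(w_s * sr)
        tt <- (seq_len(n_w) - 1L) / sr
        # damped broadband oscillation (sharp onset, ringing decay)
        shape <- exp(-tt / (w_s / 4)) * sin(2 * pi * tt / (w_s / 3))
        for (k in seq_along(centers)) {
          for (ci in seq_along(chans)) {
            tstart <- centers[k] + jit[ci, k]
            j0 <- round(tstart * sr) + 1L
            v[chans[ci] + 1L, ] <- add_at(v[chans[ci] + 1L, ], j0,
                                          spec$amplitude_uv * shape)
            add_reg(chans[ci], tstart, tstart + w_s / 4, tstart + w_s,
                    2 * spec$amplitude_uv)
          }
        }
      },
      INDUCTIVE = {
        if (length(chans) < 2L)
          stop("INDUCTIVE injection needs a readout group of >= 2 channels")
        nn <- i1 - i0 + 1L
        shared <- with_stream(seed, 4L, {
          w <- stats::rnorm(nn)
          # band-limit to the LFP range so it mimics oscillations
          sm <- stats::filter(w, rep(1 / 64, 64), circular = TRUE)
          as.numeric(sm) / stats::sd(sm) * spec$amplitude_uv
        })
        for (ch in chans) {
          v[ch + 1L, i0:i1] <- v[ch + 1L, i0:i1] + shared
          add_reg(ch, win[1L], mean(win), win[2L],
                  max(shared) - min(shared))
        }
      },
      SPURIOUS_SPIKE = {
        tmpl <- spike_template(spec$amplitude_uv, spec$spike_width_s, sr)
        period <- 1 / spec$rate_hz
        starts0 <- with_stream(seed, 5L,
                               stats::runif(length(chans), 0, period))
        for (ci in seq_along(chans)) {
          st <- seq(win[1L] + starts0[ci], win[2L] - 2 * spec$spike_width_s,
                    by = period)
          for (ts in st) {
            j0 <- round(ts * sr) + 1L
            v[chans[ci] + 1L, ] <- add_at(v[chans[ci] + 1L, ], j0, tmpl)
            add_reg(chans[ci], ts, ts + (which.min(tmpl) - 1L) / sr,
                    ts + length(tmpl) / sr, spec$amplitude_uv,
                    modality = "SPIKE")
          }
        }
      },
      CALIBRATION = {
        for (ch in chans) {
          seg <- v[ch + 1L, i0:i1] + spec$dc_offset_uv
          if (is.finite(spec$saturation_uv))
            seg <- pmin(pmax(seg, -spec$saturation_uv), spec$saturation_uv)
          v[ch + 1L, i0:i1] <- seg
          add_reg(ch, win[1L], mean(win), win[2L], abs(spec$dc_offset_uv))
        }
      },
      WHITE = {
        nz <- with_stream(seed, 6L,
          matrix(stats::rnorm(length(chans) * (i1 - i0 + 1L), 0,
                              spec$amplitude_uv), length(chans)))
        v[chans + 1L, i0:i1] <- v[chans + 1L, i0:i1] + nz
        for (ch in chans)
          add_reg(ch, win[1L], mean(win), win[2L], spec$amplitude_uv,
                  category = "GENERIC")
      })
  }

  registry <- if (length(reg)) {
    df <- do.call(rbind, reg)
    mea_events(seq_len(nrow(df)), df$channel, df$modality, df$t_on,
               df$t_peak, df$t_off, df$amplitude_uv,
               label = rep("NOISE", nrow(df)),
               noise_category = df$noise_category)
  } else mea_events()

  list(recording = mea_recording(v, sr, rec$geometry, t0 = rec$t0),
       registry = registry)
}

#' Simulate a full ground-truth benchmark recording
#'
#' Runs [generate_clean()] and then applies every noise injection in
#' `config$noise`, concatenating their registries. Deterministic in
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `recording` (noisy), `clean_recording` (pre-injection,
#'   background noise included), `true_events`, `injected_noise` (registry
#'   with unique ids) and `config`.
#' @export
simulate_recording <- function(config) {
  base <- generate_clean(config)
  rec <- base$recording
  regs <- list()
  for (k in seq_along(config$noise)) {
    out <- inject_noise(rec, config$noise[[k]], seed = config$seed + 100L * k)
    rec <- out$recording
    regs[[k]] <- out$registry
  }
  injected <- if (length(regs)) do.call(ev_bind, regs) else mea_events()
  if (nrow(injected)) injected$event_id <- seq_len(nrow(injected))
  list(recording = rec, clean_recording = base$recording,
       true_events = base$true_events, injected_noise = injected,
       config = config)
}
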