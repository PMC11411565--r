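#' Configuration of the synthetic HD-MEA recording generator
#'
#' Defines the study conditions the simulator emulates: a layered slice on a
#' rectangular electrode grid, per-region propagating LFP deflections,
#' bursty multi-unit spike trains on a subset of electrodes, Gaussian
#' background noise, and an optional list of noise injections drawn from the
#' five-category taxonomy (50 Hz line pickup, mechanical/perfusion
#' transients, inductive coupling, spurious spike trains, calibration
#' faults). A single integer seed fixes the entire output; every stochastic
#' stage derives its own stream from it.
#'
#' @param n_rows,n_cols,pitch electrode grid (defaults 64 x 64, 42 um).
#' @param duration recording length in seconds.
#' @param sampling_rate Hz per electrode (chip default 14 kHz).
#' @param regions list of regions from [synth_region()]. Default: one region
#'   spanning the full grid.
#' @param spike_channels 0-based channels carrying spike trains, or NULL for
#'   none.
#' @param spike_rate mean spike rate per active channel (Hz).
#' @param burst_prob probability that a spike seeds a burst.
#' @param burst_n spikes per burst.
#' @param burst_isi intra-burst inter-spike interval (s).
#' @param spike_p2p_uv,spike_width_s biphasic spike template peak-to-peak
#'   amplitude (uV) and total width (s).
#' @param spike_amp_cv coefficient of variation of spike amplitudes
#'   (physiological trains vary; artifact trains do not).
#' @param background_sd_uv white background noise SD (uV).
#' @param noise list of [noise_spec()] injections applied after the clean
#'   signal is built.
#' @param seed integer master seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_rows = 64L, n_cols = 64L, pitch = 42,
                         duration = 10, sampling_rate = 14000,
                         regions = NULL,
                         spike_channels = NULL, spike_rate = 2,
                         burst_prob = 0.2, burst_n = 3L, burst_isi = 0.01,
                         spike_p2p_uv = 120, spike_width_s = 0.0012,
                         spike_amp_cv = 0.15,
                         background_sd_uv = 5,
                         noise = list(), seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (spike_rate < 0 || burst_prob < 0) stop("rates must be >= 0")
  if (is.null(regions))
    regions <- list(synth_region("ALL", 0L, n_rows - 1L, 0L, n_cols - 1L))
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              pitch = pitch, duration = duration,
              sampling_rate = sampling_rate, regions = regions,
              spike_channels = if (is.null(spike_channels)) integer()
                               else as.integer(spike_channels),
              spike_rate = spike_rate, burst_prob = burst_prob,
              burst_n = as.integer(burst_n), burst_isi = burst_isi,
              spike_p2p_uv = spike_p2p_uv, spike_width_s = spike_width_s,
              spike_amp_cv = spike_amp_cv,
              background_sd_uv = background_sd_uv,
              noise = noise, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Rectangular region of the simulated slice
#'
#' @param label region name (e.g. "DG", "CA1", "GL").
#' @param row0,row1,col0,col1 inclusive 0-based grid bounds.
#' @param lfp_rate network LFP events per second initiated in this region.
#' @param lfp_amp_uv length-2 amplitude range (uV, peak-to-peak) of LFP
#'   deflections.
#' @param lfp_dur_s length-2 duration range (s).
#' @param prop_speed_um_ms propagation speed of the deflection front.
#' @param prop_dir_deg propagation direction, degrees counterclockwise from
#'   +x (0 = left to right across columns).
#' @return a `synth_region` list.
#' @export
synth_region <- function(label, row0, row1, col0, col1,
                         lfp_rate = 0.5, lfp_amp_uv = c(150, 300),
                         lfp_dur_s = c(0.15, 0.4),
                         prop_speed_um_ms = 50, prop_dir_deg = 0) {
  stopifnot(row0 <= row1, col0 <= col1, lfp_rate >= 0,
            all(lfp_amp_uv > 0), all(lfp_dur_s > 0), prop_speed_um_ms > 0)
  list(label = label, row0 = as.integer(row0), row1 = as.integer(row1),
       col0 = as.integer(col0), col1 = as.integer(col1),
       lfp_rate = lfp_rate, lfp_amp_uv = lfp_amp_uv, lfp_dur_s = lfp_dur_s,
       prop_speed_um_ms = prop_speed_um_ms, prop_dir_deg = prop_dir_deg)
}

# run expr with a derived RNG stream, restoring global RNG state afterwards
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

region_channels <- function(reg, geom) {
  rows <- reg$row0:reg$row1
  cols <- reg$col0:reg$col1
  if (reg$row1 >= geom$n_rows || reg$col1 >= geom$n_cols)
    stop(sprintf("region %s lies outside the %d x %d grid", reg$label,
                 geom$n_rows, geom$n_cols))
  as.integer(outer(rows * geom$n_cols, cols, "+"))
}

#' Per-channel region labels implied by a synth configuration
#' @param config a `synth_config`.
#' @return character vector of per-channel labels ("UNASSIGNED" outside all
#'   regions; later regions override earlier on overlap).
#' @export
synth_region_map <- function(config) {
  geom <- make_geometry(config$n_rows, config$n_cols, config$pitch)
  out <- rep("UNASSIGNED", n_channels(geom))
  for (reg in config$regions)
    out[region_channels(reg, geom) + 1L] <- reg$label
  out
}

# biphasic spike template: negative lobe then a smaller positive lobe
spike_template <- function(p2p, width_s, sr) {
  n <- max(6L, round(width_s * sr))
  n_neg <- max(3L, round(0.55 * n))
  n_pos <- n - n_neg
  a_neg <- p2p / 1.5
  a_pos <- p2p - a_neg
  c(-a_neg * sin(pi * seq_len(n_neg) / (n_neg + 1L)),
    a_pos * sin(pi * seq_len(n_pos) / (n_pos + 1L)))
}

add_at <- function(trace, start_idx, wave) {
  n <- length(trace)
  w0 <- max(1L, start_idx); w1 <- min(n, start_idx + length(wave) - 1L)
  if (w0 > w1) return(trace)
  trace[w0:w1] <- trace[w0:w1] + wave[(w0 - start_idx + 1L):(w1 - start_idx + 1L)]
  trace
}

#' Generate a clean (noise-free) ground-truth recording
#'
#' Builds the configured propagating LFP deflections (Gaussian-windowed
#' negative deflections whose onset is delayed across the grid by
#' distance/speed along the region's propagation direction) and bursty spike
#' trains, adds white background noise at the configured SD, and registers
#' every injected event in the ground-truth table.
#'
#' @param config a [synth_config()].
#' @return list with `recording` (an `mea_recording`), `true_events` (an
#'   `mea_events` with `label = "SIGNAL"`) and `clean_voltages` (the
#'   pre-background-noise voltage matrix).
#' @export
generate_clean <- function(config) {
  geom <- make_geometry(config$n_rows, config$n_cols, config$pitch)
  sr <- config$sampling_rate
  n_ch <- n_channels(geom)
  n_s <- round(config$duration * sr)
  v <- matrix(0, n_ch, n_s)

  rows <- list(); next_id <- 1L

  # --- propagating LFP deflections, one Poisson stream per region
  for (ri in seq_along(config$regions)) {
    reg <- config$regions[[ri]]
    chans <- region_channels(reg, geom)
    ev <- with_stream(config$seed, 1000L + ri, {
      n_ev <- stats::rpois(1L, reg$lfp_rate * config$duration)
      if (n_ev == 0L) NULL else data.frame(
        t0 = sort(stats::runif(n_ev, 0.05 * config$duration,
                               0.9 * config$duration)),
        amp = stats::runif(n_ev, reg$lfp_amp_uv[1L], reg$lfp_amp_uv[2L]),
        dur = stats::runif(n_ev, reg$lfp_dur_s[1L], reg$lfp_dur_s[2L]),
        jit = I(replicate(n_ev, stats::rnorm(length(chans), 1, 0.05),
                          simplify = FALSE)))
    })
    if (is.null(ev)) next
    dir_rad <- reg$prop_dir_deg * pi / 180
    proj <- geom$positions[chans + 1L, 1L] * cos(dir_rad) +
      geom$positions[chans + 1L, 2L] * sin(dir_rad)
    delay_s <- (proj - min(proj)) / reg$prop_speed_um_ms / 1000
    for (k in seq_len(nrow(ev))) {
      for (ci in seq_along(chans)) {
        tc <- ev$t0[k] + delay_s[ci] + ev$dur[k] / 2
        amp <- max(1, ev$amp[k] * ev$jit[[k]][ci])
        sig <- ev$dur[k] / 6
        i0 <- round((tc - ev$dur[k] / 2) * sr) + 1L
        tt <- (seq_len(round(ev$dur[k] * sr)) - 1L) / sr - ev$dur[k] / 2
        v[chans[ci] + 1L, ] <- add_at(v[chans[ci] + 1L, ], i0,
                                      -amp * exp(-tt^2 / (2 * sig^2)))
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = next_id, channel = chans[ci], modality = "LFP",
          t_on = tc - ev$dur[k] / 2, t_peak = tc, t_off = tc + ev$dur[k] / 2,
          amplitude_uv = amp)
        next_id <- next_id + 1L
      }
    }
  }

  # --- bursty spike trains on the configured channels
  if (length(config$spike_channels) && config$spike_rate > 0) {
    tmpl_n <- length(spike_template(1, config$spike_width_s, sr))
    for (ci in seq_along(config$spike_channels)) {
      ch <- config$spike_channels[ci]
      times <- with_stream(config$seed, 20000L + ch, {
        base <- cumsum(stats::rexp(ceiling(config$spike_rate *
                                             config$duration * 3) + 10,
                                   config$spike_rate))
        base <- base[base < config$duration - 2 * config$spike_width_s]
        extra <- unlist(lapply(base, function(tb) {
          if (config$burst_prob > 0 &&
              stats::runif(1) < config$burst_prob)
            tb + config$burst_isi * seq_len(config$burst_n - 1L)
          else numeric()
        }))
        amps <- NULL
        all_t <- sort(c(base, extra))
        all_t <- all_t[all_t < config$duration - 2 * config$spike_width_s]
        # enforce a 3 ms minimum separation so templates do not overlap
        if (length(all_t) > 1L)
          all_t <- all_t[c(TRUE, diff(all_t) >= 0.003)]
        list(t = all_t,
             a = config$spike_p2p_uv *
               pmax(0.3, stats::rnorm(length(all_t), 1, config$spike_amp_cv)))
      })
      for (k in seq_along(times$t)) {
        tmpl <- spike_template(times$a[k], config$spike_width_s, sr)
        i0 <- round(times$t[k] * sr) + 1L
        v[ch + 1L, ] <- add_at(v[ch + 1L, ], i0, tmpl)
        t_peak <- times$t[k] + (which.min(tmpl) - 1L) / sr
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = next_id, channel = ch, modality = "SPIKE",
          t_on = times$t[k], t_peak = t_peak,
          t_off = times$t[k] + tmpl_n / sr, amplitude_uv = times$a[k])
        next_id <- next_id + 1L
      }
    }
  }

  clean <- v
  if (config$background_sd_uv > 0) {
    v <- v + with_stream(config$seed, 999L,
                         matrix(stats::rnorm(length(v), 0,
                                             config$background_sd_uv),
                                nrow(v), ncol(v)))
  }

  te <- if (length(rows)) {
    df <- do.call(rbind, rows)
    mea_events(df$event_id, df$channel, df$modality, df$t_on, df$t_peak,
               df$t_off, df$amplitude_uv,
               label = rep("SIGNAL", nrow(df)))
  } else mea_events()

  list(recording = mea_recording(v, sr, geom),
       true_events = te, clean_voltages = float32_quantize(clean))
}
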