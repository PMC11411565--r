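EVENT_FEATURE_NAMES <- c("amplitude", "duration", "dominant_frequency",
                         "spectral_concentration", "shape_irregularity",
                         "asymmetry")
CHANNEL_FEATURE_NAMES <- c("firing_rate", "burst_frequency", "synchrony",
                           "amplitude_cv", "isi_cv")

#' Per-event waveform features
#'
#' Computes, for every event carrying a waveform snippet, the feature set
#' the noise/signal template is built on:
#' \describe{
#'   \item{amplitude}{peak-to-peak of the snippet (uV).}
#'   \item{duration}{`t_off - t_on` (s).}
#'   \item{dominant_frequency}{periodogram peak of the snippet, DC
#'     excluded (Hz).}
#'   \item{spectral_concentration}{fraction of snippet power within a
#'     band around the dominant frequency: +/- 1 Hz for LFP, +/- 100 Hz
#'     for spikes.}
#'   \item{shape_irregularity}{1 minus the fraction of snippet energy
#'     captured by its best-fitting single-lobe Gaussian; smooth
#'     physiological deflections score low, jagged artifacts high.}
#'   \item{asymmetry}{(positive-phase area - negative-phase area) /
#'     total absolute area, in [-1, 1], measured about the snippet
#'     median so a DC offset does not change it.}
#' }
#'
#' @param events an `mea_events` with waveform snippets of >= 8 samples.
#' @return data.frame with `event_id` plus one column per feature.
#' @export
event_features <- function(events) {
  validate_events(events)
  if (nrow(events) == 0L)
    return(cbind(data.frame(event_id = integer()),
                 stats::setNames(as.data.frame(
                   matrix(numeric(), 0, length(EVENT_FEATURE_NAMES))),
                   EVENT_FEATURE_NAMES)))
  out <- lapply(seq_len(nrow(events)), function(i) {
    w <- events$waveform[[i]]
    if (is.null(w) || length(w) < 8L)
      stop(sprintf("event %d: waveform snippet missing or shorter than 8 samples",
                   events$event_id[i]))
    sr <- events$snippet_rate[i]
    spec <- snippet_spectrum(w, sr)
    half_band <- if (events$modality[i] == "LFP") 1 else 100
    inband <- abs(spec$freq - spec$freq[which.max(spec$power)]) <= half_band
    centered <- w - stats::median(w)
    pos <- sum(pmax(centered, 0)); neg <- sum(pmax(-centered, 0))
    data.frame(
      event_id = events$event_id[i],
      amplitude = max(w) - min(w),
      duration = events$t_off[i] - events$t_on[i],
      dominant_frequency = spec$freq[which.max(spec$power)],
      spectral_concentration =
        if (sum(spec$power) > 0) sum(spec$power[inband]) / sum(spec$power)
        else 0,
      shape_irregularity = shape_irregularity(w, sr),
      asymmetry = if (pos + neg > 0) (pos - neg) / (pos + neg) else 0)
  })
  do.call(rbind, out)
}

snippet_spectrum <- function(w, sr) {
  n <- length(w)
  p <- Mod(stats::fft(w - mean(w)))^2
  k <- seq_len(floor(n / 2))          # positive frequencies, DC excluded
  list(freq = k / n * sr, power = p[k + 1L])
}

# 1 - max over (mu, s) of cos^2 angle between snippet and a Gaussian lobe
shape_irregularity <- function(w, sr) {
  n <- length(w)
  stride <- max(1L, ceiling(n / 256))      # cap the fit problem size
  x <- w[seq(1L, n, by = stride)]
  x <- x - stats::median(x)
  nx <- length(x)
  if (sum(x^2) == 0) return(0)
  tt <- seq_len(nx)
  proj <- function(par) {
    mu <- par[1L]; s <- exp(par[2L])
    g <- exp(-(tt - mu)^2 / (2 * s^2))
    cp <- sum(x * g)^2 / (sum(g^2) * sum(x^2))
    cm <- cp  # sign-free: |cos angle|^2 covers negative lobes too
    -max(cp, cm)
  }
  init <- c(which.max(abs(x)), log(max(2, nx / 6)))
  fit <- stats::optim(init, proj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  max(0, min(1, 1 + fit$value))
}

#' Per-channel activity features
#'
#' @param events an `mea_events` (any channels; only `channel` rows used).
#' @param channel 0-based channel index.
#' @param duration recording duration (s), > 0.
#' @param network_events data.frame of network-event windows from
#'   [detect_network_events()] (may be empty).
#' @param burst_isi_max maximum inter-event interval inside a burst (s);
#'   a burst is a run of >= 3 events with all gaps below this.
#' @return one-row data.frame: `firing_rate` (events/s), `burst_frequency`
#'   (bursts/s), `synchrony` (fraction of the channel's events inside any
#'   network-event window), `amplitude_cv`, `isi_cv`.
#' @export
channel_features <- function(events, channel, duration,
                             network_events = NULL, burst_isi_max = 0.1) {
  if (duration <= 0) stop("duration must be > 0")
  ev <- events[events$channel == channel, , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L)
    return(data.frame(channel = channel, firing_rate = 0,
                      burst_frequency = 0, synchrony = 0,
                      amplitude_cv = 0, isi_cv = 0))
  tp <- sort(ev$t_peak)
  isi <- diff(tp)
  # bursts: maximal runs of >= 3 events with gaps <= burst_isi_max
  n_bursts <- 0L
  if (length(isi)) {
    r <- rle(isi <= burst_isi_max)
    n_bursts <- sum(r$values & r$lengths >= 2L)  # k gaps = k+1 events
  }
  sync <- 0
  if (!is.null(network_events) && nrow(network_events))
    sync <- mean(vapply(tp, function(t)
      any(t >= network_events$t_start & t <= network_events$t_end),
      logical(1L)))
  cv <- function(x) {
    if (length(x) < 2L || mean(x) == 0) return(0)
    stats::sd(x) / mean(x)
  }
  data.frame(channel = channel, firing_rate = n / duration,
             burst_frequency = n_bursts / duration, synchrony = sync,
             amplitude_cv = cv(ev$amplitude_uv), isi_cv = cv(isi))
}

#' Network events: windows where many electrodes fire together
#'
#' Slides a window over the event peak times; any window in which at least
#' `min_coactive` distinct channels have an event is a network event;
#' overlapping qualifying windows are merged.
#'
#' @param events an `mea_events`.
#' @param geometry the recording's `mea_geometry` (used for the default
#'   `min_coactive` of 5% of channels).
#' @param min_coactive minimum number of distinct co-active channels.
#' @param window window length in seconds (50 ms for LFP and 10 ms for
#'   spike analyses by convention).
#' @return data.frame with `t_start`, `t_end`, `n_coactive`.
#' @export
detect_network_events <- function(events, geometry,
                                  min_coactive = NULL, window = 0.05) {
  if (window <= 0) stop("window must be > 0")
  if (is.null(min_coactive))
    min_coactive <- max(2L, ceiling(0.05 * n_channels(geometry)))
  if (nrow(events) == 0L)
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      n_coactive = integer()))
  o <- order(events$t_peak)
  tp <- events$t_peak[o]; ch <- events$channel[o]
  n <- length(tp)
  qual <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {   # window anchored at each event
    while (tp[j] < tp[i] - 1e-12) j <- j + 1L
    k <- i
    while (k < n && tp[k + 1L] <= tp[i] + window) k <- k + 1L
    if (length(unique(ch[i:k])) >= min_coactive) qual[i] <- TRUE
  }
  if (!any(qual))
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      n_coactive = integer()))
  st <- tp[qual]; en <- tp[qual] + window
  grp <- cumsum(c(0L, st[-1L] > cummax(en)[-length(en)]))
  out <- lapply(split(seq_along(st), grp), function(ii) {
    t0 <- min(st[ii]); t1 <- max(en[ii])
    data.frame(t_start = t0, t_end = t1,
               n_coactive = length(unique(ch[tp >= t0 & tp <= t1])))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the network-derived noise/signal template
#'
#' For every event and channel feature the template stores an acceptance
#' interval `median +/- k_mad * MAD` (MAD scaled for Gaussian consistency,
#' as in [stats::mad()]), except `duration`, whose interval is the observed
#' min-max range widened by 10%. Features with zero MAD collapse to the
#' observed value plus a machine-epsilon-scaled pad, so any differing value
#' falls outside. The number of co-active electrodes per network event is
#' bounded the same robust way.
#'
#' @param event_feats data.frame from [event_features()] (>= 10 rows).
#' @param channel_feats data.frame of [channel_features()] rows.
#' @param network_events data.frame from [detect_network_events()], or NULL.
#' @param k_mad interval half-width in MADs (default 3).
#' @param provenance optional free-text provenance string stored in the
#'   template.
#' @return a `noise_template`: list of per-feature `{low, high}` bounds.
#' @export
build_template <- function(event_feats, channel_feats,
                           network_events = NULL, k_mad = 3,
                           provenance = "") {
  if (is.null(event_feats) || nrow(event_feats) < 10L)
    stop("insufficient events to build a template (need >= 10)")
  pad_interval <- function(x) {
    med <- stats::median(x); s <- stats::mad(x)
    if (s == 0)   # quantized features can zero the MAD while still varying
      s <- stats::IQR(x) / 1.349
    if (s == 0) {
      pad <- max(abs(med), 1) * sqrt(.Machine$double.eps)
      return(c(low = med - pad, high = med + pad))
    }
    c(low = med - k_mad * s, high = med + k_mad * s)
  }
  ev_b <- lapply(EVENT_FEATURE_NAMES, function(f) {
    x <- event_feats[[f]]
    if (f == "duration") {
      w <- 0.05 * (max(x) - min(x))
      if (w == 0) w <- max(abs(x[1L]), 1) * sqrt(.Machine$double.eps)
      c(low = min(x) - w, high = max(x) + w)
    } else pad_interval(x)
  })
  names(ev_b) <- EVENT_FEATURE_NAMES
  ch_b <- NULL
  if (!is.null(channel_feats) && nrow(channel_feats)) {
    ch_b <- lapply(CHANNEL_FEATURE_NAMES, function(f)
      pad_interval(channel_feats[[f]]))
    names(ch_b) <- CHANNEL_FEATURE_NAMES
  }
  nc_b <- NULL
  if (!is.null(network_events) && nrow(network_events))
    nc_b <- pad_interval(network_events$n_coactive)
  structure(list(event = ev_b, channel = ch_b, n_coactive = nc_b,
                 k_mad = k_mad, provenance = provenance),
            class = "noise_template")
}

#' @export
print.noise_template <- function(x, ...) {
  cat("noise_template (k_mad =", x$k_mad, ")\n")
  for (f in names(x$event))
    cat(sprintf("  event %-22s [%.4g, %.4g]\n", f, x$event[[f]]["low"],
                x$event[[f]]["high"]))
  for (f in names(x$channel))
    cat(sprintf("  channel %-20s [%.4g, %.4g]\n", f, x$channel[[f]]["low"],
                x$channel[[f]]["high"]))
  invisible(x)
}

#' Serialize / reload a noise template
#'
#' JSON with full double precision, so reloaded bounds are bit-identical
#' and classification decisions do not change across save/load.
#'
#' @param template a `noise_template`.
#' @param path file path.
#' @export
write_template <- function(template, path) {
  # bounds formatted at 17 significant digits so doubles survive exactly
  num <- function(x) sprintf("%.17g", x)
  block <- function(b, indent) {
    if (is.null(b)) return("null")
    rows <- vapply(names(b), function(f)
      sprintf("%s\"%s\": [%s, %s]", indent, f, num(b[[f]]["low"]),
              num(b[[f]]["high"])), character(1L))
    sprintf("{\n%s\n%s}", paste(rows, collapse = ",\n"),
            substr(indent, 1L, nchar(indent) - 2L))
  }
  txt <- sprintf(paste0(
    "{\n  \"event\": %s,\n  \"channel\": %s,\n  \"n_coactive\": %s,\n",
    "  \"k_mad\": %s,\n  \"provenance\": %s\n}"),
    block(template$event, "    "), block(template$channel, "    "),
    if (is.null(template$n_coactive)) "null" else
      sprintf("[%s, %s]", num(template$n_coactive["low"]),
              num(template$n_coactive["high"])),
    num(template$k_mad),
    jsonlite::toJSON(template$provenance %||% "", auto_unbox = TRUE))
  writeLines(txt, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_template
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  iv_of <- function(iv) {  # stored as [low, high]
    iv <- unlist(iv)
    c(low = as.numeric(iv[[1L]]), high = as.numeric(iv[[2L]]))
  }
  fix <- function(b) if (is.null(b)) NULL else lapply(b, iv_of)
  structure(list(event = fix(raw$event), channel = fix(raw$channel),
                 n_coactive = if (is.null(raw$n_coactive)) NULL else
                   iv_of(raw$n_coactive),
                 k_mad = raw$k_mad, provenance = raw$provenance),
            class = "noise_template")
}
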