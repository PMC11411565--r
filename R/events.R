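MODALITIES <- c("LFP", "SPIKE")
EVENT_LABELS <- c("UNLABELED", "SIGNAL", "NOISE")
NOISE_CATEGORIES <- c("LINE", "MECHANICAL", "INDUCTIVE", "SPURIOUS_SPIKE",
                      "CALIBRATION", "GENERIC")

#' Event table for detected or injected LFP/spike events
#'
#' A data.frame (class `mea_events`) with one row per event and columns
#' `event_id`, `channel` (0-based), `modality` ("LFP"/"SPIKE"), `t_on`,
#' `t_peak`, `t_off` (seconds; half-open window `[t_on, t_off)`),
#' `amplitude_uv` (peak-to-peak), `label` ("UNLABELED"/"SIGNAL"/"NOISE"),
#' `noise_category` (NA unless label is NOISE), `snippet_rate` (Hz) and a
#' list-column `waveform` holding the voltage snippet of each event.
#'
#' @param event_id unique integer ids.
#' @param channel 0-based channel index per event.
#' @param modality "LFP" or "SPIKE".
#' @param t_on,t_peak,t_off event window in seconds, `t_on <= t_peak <= t_off`.
#' @param amplitude_uv peak-to-peak amplitude, >= 0.
#' @param label event label; defaults to "UNLABELED".
#' @param noise_category noise class, only when `label == "NOISE"`.
#' @param waveform list of numeric snippet vectors (or NULL).
#' @param snippet_rate snippet sampling rate in Hz.
#' @return an `mea_events` data.frame.
#' @export
mea_events <- function(event_id = integer(), channel = integer(),
                       modality = character(), t_on = numeric(),
                       t_peak = numeric(), t_off = numeric(),
                       amplitude_uv = numeric(),
                       label = rep("UNLABELED", length(event_id)),
                       noise_category = rep(NA_character_, length(event_id)),
                       waveform = NULL, snippet_rate = NA_real_) {
  n <- length(event_id)
  if (is.null(waveform)) waveform <- rep(list(NULL), n)
  df <- data.frame(
    event_id = as.integer(event_id), channel = as.integer(channel),
    modality = as.character(modality),
    t_on = as.numeric(t_on), t_peak = as.numeric(t_peak),
    t_off = as.numeric(t_off), amplitude_uv = as.numeric(amplitude_uv),
    label = as.character(label),
    noise_category = as.character(noise_category),
    snippet_rate = rep_len(as.numeric(snippet_rate), n),
    stringsAsFactors = FALSE)
  df$waveform <- waveform
  class(df) <- c("mea_events", "data.frame")
  validate_events(df)
}

validate_events <- function(ev, context = "event table") {
  stopifnot(is.data.frame(ev))
  if (nrow(ev) == 0L) return(invisible(ev))
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("%s: %s (row %d)", context, msg, i[1L]))
  }
  if (anyDuplicated(ev$event_id))
    stop(sprintf("%s: event_id values must be unique", context))
  bad(!ev$modality %in% MODALITIES, "modality must be LFP or SPIKE")
  bad(ev$t_on > ev$t_peak | ev$t_peak > ev$t_off,
      "need t_on <= t_peak <= t_off")
  bad(ev$amplitude_uv < 0, "amplitude must be >= 0")
  bad(!ev$label %in% EVENT_LABELS, "unknown label")
  bad(ev$label != "NOISE" & !is.na(ev$noise_category),
      "noise_category may only be set when label is NOISE")
  bad(ev$label == "NOISE" & !is.na(ev$noise_category) &
        !ev$noise_category %in% NOISE_CATEGORIES,
      "unknown noise_category")
  invisible(ev)
}

#' @export
print.mea_events <- function(x, ...) {
  cat(sprintf("mea_events: %d events (%d LFP, %d SPIKE; %d SIGNAL, %d NOISE)\n",
              nrow(x), sum(x$modality == "LFP"), sum(x$modality == "SPIKE"),
              sum(x$label == "SIGNAL"), sum(x$label == "NOISE")))
  if (nrow(x)) print(utils::head(as.data.frame(x)[
    setdiff(names(x), "waveform")], 10L))
  invisible(x)
}

ev_csv_cols <- c("event_id", "channel", "modality", "t_on", "t_peak",
                 "t_off", "amplitude_uv", "label", "noise_category")

#' Read / write event tables as CSV (+ waveform sidecar)
#'
#' The main CSV holds columns `event_id,channel,modality,t_on,t_peak,t_off,
#' amplitude_uv,label,noise_category`. Waveform snippets go to a sidecar CSV
#' (`<path>.waveforms.csv`) in long format keyed by `event_id`, so both
#' files stay plain text. Numeric fields are printed with 17 significant
#' digits so doubles round-trip exactly.
#'
#' @param path CSV path for the event table.
#' @return `read_events`: an `mea_events`; `write_events`: `path`, invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          event_id = "integer", channel = "integer",
                          modality = "character", t_on = "numeric",
                          t_peak = "numeric", t_off = "numeric",
                          amplitude_uv = "numeric", label = "character",
                          noise_category = "character"))
  if (!setequal(names(df), ev_csv_cols))
    stop(sprintf("%s: expected columns %s", path,
                 paste(ev_csv_cols, collapse = ",")))
  df$noise_category[df$noise_category %in% c("", "NA")] <- NA_character_
  # invariants row by row, reporting the offending CSV line (header = line 1)
  viol <- which(df$t_on > df$t_peak | df$t_peak > df$t_off)
  if (length(viol))
    stop(sprintf("%s: t_on <= t_peak <= t_off violated at line %d",
                 path, viol[1L] + 1L))
  viol <- which(df$amplitude_uv < 0)
  if (length(viol))
    stop(sprintf("%s: negative amplitude at line %d", path, viol[1L] + 1L))
  wf <- rep(list(NULL), nrow(df))
  snippet_rate <- rep(NA_real_, nrow(df))
  side <- paste0(path, ".waveforms.csv")
  if (file.exists(side) && nrow(df)) {
    sw <- utils::read.csv(side, stringsAsFactors = FALSE)
    sp <- split(sw, sw$event_id)
    idx <- match(as.integer(names(sp)), df$event_id)
    for (k in seq_along(sp)) {
      if (is.na(idx[k])) next
      wf[[idx[k]]] <- sp[[k]]$voltage_uv[order(sp[[k]]$sample_idx)]
      snippet_rate[idx[k]] <- sp[[k]]$snippet_rate[1L]
    }
  }
  mea_events(df$event_id, df$channel, df$modality, df$t_on, df$t_peak,
             df$t_off, df$amplitude_uv, df$label, df$noise_category,
             waveform = wf, snippet_rate = snippet_rate)
}

#' @rdname read_events
#' @param ev an `mea_events` table.
#' @export
write_events <- function(ev, path) {
  validate_events(ev)
  out <- as.data.frame(ev)[, ev_csv_cols, drop = FALSE]
  for (cc in c("t_on", "t_peak", "t_off", "amplitude_uv"))
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  has_wf <- which(!vapply(ev$waveform, is.null, logical(1L)))
  side <- paste0(path, ".waveforms.csv")
  if (length(has_wf)) {
    parts <- lapply(has_wf, function(i) {
      w <- ev$waveform[[i]]
      data.frame(event_id = ev$event_id[i],
                 snippet_rate = sprintf("%.17g", ev$snippet_rate[i]),
                 sample_idx = seq_along(w) - 1L,
                 voltage_uv = sprintf("%.17g", w))
    })
    utils::write.csv(do.call(rbind, parts), side, row.names = FALSE,
                     quote = FALSE)
  } else if (file.exists(side)) unlink(side)
  invisible(path)
}

# subset an mea_events, keeping class and list column
ev_subset <- function(ev, i) {
  out <- as.data.frame(ev)[i, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mea_events", "data.frame")
  out
}

ev_bind <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) return(mea_events())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("mea_events", "data.frame")
  out
}
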