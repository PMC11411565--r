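#' SNR in decibels
#'
#' `10 * log10(snr_linear)`.
#'
#' @param snr_linear linear SNR values, > 0.
#' @return dB values.
#' @export
snr_db <- function(snr_linear) {
  if (any(snr_linear <= 0)) stop("snr_db requires snr_linear > 0")
  10 * log10(snr_linear)
}

#' Normalized SNR difference (percent)
#'
#' `(denoised_db - raw_db) / raw_db * 100`: the relative gain of the
#' denoised over the raw SNR on the dB scale.
#'
#' @param raw_db raw-signal SNR in dB (nonzero).
#' @param denoised_db denoised-signal SNR in dB.
#' @return percent gain.
#' @export
snr_dr <- function(raw_db, denoised_db) {
  if (any(raw_db == 0))
    stop("snr_dr undefined for raw_db = 0 (zero denominator)")
  (denoised_db - raw_db) / raw_db * 100
}

#' RMS noise of a series
#'
#' `sqrt(sum(x^2) / N)`: the magnitude of the varying components of a
#' biosignal (uV on voltage series, events/s on rate series).
#'
#' @param series numeric vector, length >= 1.
#' @return the RMS value.
#' @export
rms_noise <- function(series) {
  if (length(series) == 0L) stop("rms_noise of an empty series")
  sqrt(sum(series^2) / length(series))
}

#' Per-channel SNR distribution of firing activity
#'
#' For each active channel (>= 1 event), bins the channel's events into
#' `bin`-second rate bins and returns mean(rate) / sd(rate) across the
#' time domain, using the population (divide-by-N) standard deviation.
#' Channels with zero rate variance are excluded (reported in the
#' `excluded` attribute) rather than mapped to infinity.
#'
#' @param events an `mea_events`.
#' @param duration recording duration (s); at least 2 bins must fit.
#' @param bin bin width in seconds (50 ms for LFP, 10 ms for spikes by
#'   convention).
#' @return data.frame `channel`, `snr` for the active channels with
#'   positive rate variance.
#' @export
snr_distribution <- function(events, duration, bin = 0.05) {
  n_bins <- floor(duration / bin)
  if (n_bins < 2L) stop("need at least 2 time bins")
  chans <- sort(unique(events$channel))
  res <- lapply(chans, function(ch) {
    tp <- events$t_peak[events$channel == ch]
    cnt <- tabulate(pmin(n_bins, floor(tp / bin) + 1L), nbins = n_bins)
    rate <- cnt / bin
    sdev <- sqrt(mean((rate - mean(rate))^2))
    data.frame(channel = ch, snr = if (sdev > 0) mean(rate) / sdev else NA)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- data.frame(channel = integer(), snr = numeric())
  excluded <- res$channel[is.na(res$snr)]
  out <- res[!is.na(res$snr), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Two-sample statistical comparison
#'
#' Thin wrapper over the standard two-sample Kolmogorov-Smirnov test and
#' one-way ANOVA used to compare SNR/RMS distributions between conditions.
#'
#' @param sample_a,sample_b numeric samples (>= 2 values each). For ANOVA
#'   with more than two groups, pass a list of samples as `sample_a` and
#'   leave `sample_b` NULL.
#' @param test `"KS"` or `"ANOVA"`.
#' @return list with `statistic` (KS D or ANOVA F) and `p_value`.
#' @export
stat_compare <- function(sample_a, sample_b = NULL, test = c("KS", "ANOVA")) {
  test <- match.arg(test)
  groups <- if (is.list(sample_a)) sample_a else list(sample_a, sample_b)
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each sample needs at least 2 values")
  if (test == "KS") {
    if (length(groups) != 2L) stop("KS compares exactly two samples")
    r <- suppressWarnings(stats::ks.test(groups[[1L]], groups[[2L]]))
    list(statistic = unname(r$statistic), p_value = r$p.value)
  } else {
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    a <- summary(stats::aov(y ~ g))[[1L]]
    list(statistic = a[["F value"]][1L], p_value = a[["Pr(>F)"]][1L])
  }
}
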