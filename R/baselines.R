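# db4 analysis low-pass coefficients (8 taps); high-pass and synthesis
# filters follow by quadrature-mirror relations.
DB4_DEC_LO <- c(-0.010597401785069032, 0.032883011666885197,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.63088076792985892,
                0.71484657055291567, 0.23037781330889651)

#' Parameters of the classical single-channel denoising baselines
#'
#' @param method one of `"FIR"`, `"SAVGOL"`, `"WAVELET"`, `"FOURIER"`.
#' @param fir_n FIR coefficient count (taps).
#' @param fir_cutoff_hz FIR low-pass cutoff.
#' @param savgol_window odd window length (samples), > `savgol_order`.
#' @param savgol_order polynomial order.
#' @param wavelet_level DWT decomposition depth (db4 family).
#' @param fourier_stopbands_hz list of length-2 stop-bands to zero out
#'   (default: 50 Hz mains and its first two harmonics, +/- 1 Hz).
#' @return a `baseline_params` list.
#' @export
baseline_params <- function(method = c("FIR", "SAVGOL", "WAVELET", "FOURIER"),
                            fir_n = 101L, fir_cutoff_hz = 100,
                            savgol_window = 11L, savgol_order = 2L,
                            wavelet_level = 4L,
                            fourier_stopbands_hz = list(c(49, 51),
                                                        c(99, 101),
                                                        c(149, 151))) {
  method <- match.arg(method)
  if (savgol_window %% 2L == 0L || savgol_window <= savgol_order)
    stop("SAVGOL window must be odd and larger than the order")
  if (wavelet_level < 1L) stop("wavelet level must be >= 1")
  structure(list(method = method, fir_n = as.integer(fir_n),
                 fir_cutoff_hz = fir_cutoff_hz,
                 savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order),
                 wavelet_level = as.integer(wavelet_level),
                 fourier_stopbands_hz = fourier_stopbands_hz),
            class = "baseline_params")
}

#' Classical denoising baselines on a single-channel trace
#'
#' The four comparators the engine is benchmarked against, each applied
#' per channel:
#' \describe{
#'   \item{FIR}{causal forward-in-time low-pass FIR filter (windowed-sinc
#'     design; output at time t depends only on samples <= t).}
#'   \item{SAVGOL}{Savitzky-Golay least-squares local polynomial
#'     smoothing.}
#'   \item{WAVELET}{db4 discrete wavelet decomposition, soft universal
#'     threshold `sigma * sqrt(2 log N)` on the detail coefficients (sigma
#'     from the MAD of the finest details), reconstruction.}
#'   \item{FOURIER}{FFT, zeroing of the configured stop-bands, inverse
#'     FFT (real part).}
#' }
#'
#' @param trace numeric voltage vector.
#' @param sampling_rate Hz.
#' @param params a [baseline_params()].
#' @return denoised trace of identical length.
#' @export
baseline_denoise <- function(trace, sampling_rate, params) {
  n <- length(trace)
  switch(params$method,
    FIR = {
      if (n <= params$fir_n) stop("trace shorter than the FIR filter")
      b <- signal::fir1(params$fir_n - 1L,
                        params$fir_cutoff_hz / (sampling_rate / 2))
      y <- stats::filter(c(rep(0, params$fir_n - 1L), trace), b,
                         method = "convolution", sides = 1L)
      as.numeric(y[params$fir_n:(n + params$fir_n - 1L)])
    },
    SAVGOL = {
      if (n <= params$savgol_window)
        stop("trace shorter than the Savitzky-Golay window")
      as.numeric(signal::sgolayfilt(trace, p = params$savgol_order,
                                    n = params$savgol_window))
    },
    WAVELET = wavelet_denoise(trace, params$wavelet_level),
    FOURIER = {
      xf <- stats::fft(trace)
      f <- (0:(n - 1L)) / n * sampling_rate
      f <- pmin(f, sampling_rate - f)
      for (sb in params$fourier_stopbands_hz)
        xf[f >= sb[1L] & f <= sb[2L]] <- 0
      Re(stats::fft(xf, inverse = TRUE)) / n
    })
}

# ---- db4 DWT, periodized boundary handling ---------------------------
# Analysis:  a[k] = sum_m dec_lo[m] x[(2k + L/2 - m) mod n]
# Synthesis: x[j] = sum_m rec_lo[m] ua[(j - m + L/2 - 1) mod n] + (hi term)
# with rec_lo = rev(dec_lo), dec_hi the quadrature mirror of dec_lo and
# ua/ud the zero-upsampled subbands. Perfect reconstruction to machine
# precision (tested), matching the usual periodization convention.

qmf_hi <- function(lo) rev(lo) * (-1)^(seq_along(lo))

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  L <- length(lo)
  # rows: output index k = 0..n/2-1; cols: filter tap m = 0..L-1
  idx <- outer(seq(0L, n - 2L, by = 2L), 0:(L - 1L),
               function(k2, m) ((k2 + L %/% 2L - m) %% n) + 1L)
  xe <- matrix(x[idx], ncol = L)
  list(a = as.numeric(xe %*% lo), d = as.numeric(xe %*% hi))
}

idwt_step <- function(a, d, lo, hi) {
  n2 <- length(a) * 2L
  L <- length(lo)
  ua <- numeric(n2); ua[seq(1L, n2, by = 2L)] <- a
  ud <- numeric(n2); ud[seq(1L, n2, by = 2L)] <- d
  rlo <- rev(lo); rhi <- rev(hi)
  idx <- outer(0:(n2 - 1L), 0:(L - 1L),
               function(j, m) ((j - m + L %/% 2L - 1L) %% n2) + 1L)
  as.numeric(matrix(ua[idx], ncol = L) %*% rlo +
             matrix(ud[idx], ncol = L) %*% rhi)
}

dwt_db4 <- function(x, level) {
  lo <- DB4_DEC_LO; hi <- qmf_hi(lo)
  details <- vector("list", level)
  a <- x
  pad <- 0L
  for (l in seq_len(level)) {
    if (length(a) %% 2L == 1L) { a <- c(a, a[length(a)]); if (l == 1L) pad <- 1L }
    s <- dwt_step(a, lo, hi)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, pad = pad, n = length(x))
}

idwt_db4 <- function(dec) {
  lo <- DB4_DEC_LO; hi <- qmf_hi(lo)
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    d <- dec$details[[l]]
    if (length(a) > length(d)) a <- a[seq_along(d)]
    a <- idwt_step(a, d, lo, hi)
  }
  a[seq_len(dec$n)]
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

wavelet_denoise <- function(trace, level = 4L) {
  dec <- dwt_db4(trace, level)
  sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(trace)))
  dec$details <- lapply(dec$details, soft_threshold, thr = thr)
  idwt_db4(dec)
}

#' Apply a baseline denoiser to every channel of a recording
#'
#' @param rec an `mea_recording`.
#' @param params a [baseline_params()].
#' @return denoised `mea_recording`.
#' @export
baseline_denoise_recording <- function(rec, params) {
  v <- t(apply(rec$voltages, 1L, baseline_denoise,
               sampling_rate = rec$sampling_rate, params = params))
  mea_recording(v, rec$sampling_rate, rec$geometry, t0 = rec$t0,
                quantize = FALSE)
}
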