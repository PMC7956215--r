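# Linear-phase FIR denoising and ECG automatic gain control.
#
# All filters are odd-length Hamming-windowed FIRs applied zero-phase:
# the signal is reflect-padded by half the filter length on both sides,
# convolved with the centered taps, and cropped back, so the output has
# the input's length and no group delay.

fir_taps <- function(kind = c("lowpass", "highpass"), cutoff, fs, taps) {
  kind <- match.arg(kind)
  if (taps < 3 || taps %% 2 == 0) stop("FIR tap count must be odd and >= 3")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly inside (0, fs/2)")
  h <- signal::fir1(taps - 1, cutoff / (fs / 2), type = "low",
                    window = signal::hamming(taps))
  h <- h / sum(h)                       # exact unit DC gain
  if (kind == "lowpass") return(h)
  # linear-phase high-pass by spectral inversion: exact zero DC gain
  h <- -h
  h[(taps + 1L) / 2L] <- h[(taps + 1L) / 2L] + 1
  h
}

apply_fir <- function(x, h) {
  n <- length(x)
  d <- (length(h) - 1L) / 2L
  if (n <= 3 * length(h))
    stop("input too short for the filter: need more than ",
         3 * length(h), " samples, got ", n)
  # reflect padding (no edge repetition)
  left <- x[(d + 1L):2L]
  right <- x[(n - 1L):(n - d)]
  xp <- c(left, x, right)
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(d + 1L):(d + n)])
}

#' Band-pass filter an ECG window
#'
#' High-pass / low-pass linear-phase FIR cascade (defaults 0.5–40 Hz,
#' 255 taps at 256 Hz) removing baseline wander and high-frequency noise
#' while preserving the QRS complex. Zero-phase application keeps R-peak
#' positions unchanged.
#'
#' @param x numeric ECG samples (mV).
#' @param fs sampling rate in Hz.
#' @param cfg a [fear_config()]; uses `ecg.highpass_hz`, `ecg.lowpass_hz`,
#'   `ecg.taps`.
#' @return Filtered samples, same length as `x`.
#' @export
filter_ecg <- function(x, fs, cfg = fear_config()) {
  cfg <- as_fear_config(cfg)
  hp <- fir_taps("highpass", cfg$ecg.highpass_hz, fs, cfg$ecg.taps)
  lp <- fir_taps("lowpass", cfg$ecg.lowpass_hz, fs, cfg$ecg.taps)
  apply_fir(apply_fir(x, hp), lp)
}

#' Low-pass filter a GSR or SKT window
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param taps odd FIR length (default 129).
#' @return Filtered samples, same length as `x`.
#' @export
filter_lowpass <- function(x, fs, cutoff_hz, taps = 129) {
  apply_fir(x, fir_taps("lowpass", cutoff_hz, fs, taps))
}

moving_max <- function(x, k) {
  # centered moving maximum, window k (odd), shrinking at the edges;
  # van Herk block decomposition, O(n)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  m <- ceiling((n + 2L * h) / k) * k
  xp <- c(rep(-Inf, h), x, rep(-Inf, m - n - h))
  blocks <- matrix(xp, nrow = k)
  pre <- apply(blocks, 2, cummax)
  suf <- apply(blocks[k:1, , drop = FALSE], 2, cummax)[k:1, , drop = FALSE]
  lo <- as.vector(suf)
  hi <- as.vector(pre)
  i <- seq_len(n)              # window start positions in the padded series
  pmax(lo[i], hi[i + k - 1L])
}

moving_mean <- function(x, k) {
  # centered moving average, window k, shrinking at the edges
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Automatic gain control for ECG
#'
#' Divides the signal by a smoothed running amplitude envelope so that beat
#' peaks sit near unit amplitude regardless of slow gain drift — a cheap
#' way to make a fixed-threshold R-peak detector robust. The envelope is
#' the moving maximum of `|x|` over `agc.window_s` seconds, smoothed by an
#' `agc.smooth_s` moving average and floored at `agc.floor_frac` of the
#' global absolute maximum (the floor stops quiet stretches from blowing
#' up noise). Peak sample positions are unchanged; the output is invariant
#' to rescaling the input.
#'
#' @param x filtered ECG samples; must not be all zero.
#' @param fs sampling rate in Hz.
#' @param cfg a [fear_config()].
#' @return Gain-normalized samples with maximum absolute value near 1.
#' @export
apply_agc <- function(x, fs, cfg = fear_config()) {
  cfg <- as_fear_config(cfg)
  gmax <- max(abs(x))
  if (gmax == 0) stop("AGC undefined for an all-zero signal")
  k <- max(3L, round(cfg$agc.window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  env <- moving_max(abs(x), k)
  ks <- max(1L, round(cfg$agc.smooth_s * fs))
  if (ks > 1) env <- moving_mean(env, ks)
  env <- pmax(env, cfg$agc.floor_frac * gmax)
  x / env
}

#' Denoise one window, all three sensors
#'
#' ECG: band-pass cascade ([filter_ecg()]) followed by automatic gain
#' control ([apply_agc()]). GSR and SKT: low-pass FIR at `gsr.lowpass_hz` /
#' `skt.lowpass_hz`.
#'
#' @param win a `"fear_window"` from [segment_trial()].
#' @param cfg a [fear_config()].
#' @return The window with filtered `ECG`, `GSR`, `SKT` vectors.
#' @export
preprocess_window <- function(win, cfg = fear_config()) {
  cfg <- as_fear_config(cfg)
  stopifnot(inherits(win, "fear_window"))
  fs <- win$sampling_rate
  win$ECG <- apply_agc(filter_ecg(win$ECG, fs, cfg), fs, cfg)
  win$GSR <- filter_lowpass(win$GSR, fs, cfg$gsr.lowpass_hz, cfg$lp.taps)
  win$SKT <- filter_lowpass(win$SKT, fs, cfg$skt.lowpass_hz, cfg$lp.taps)
  win
}
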