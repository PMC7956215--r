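#' Segment a trimmed trial into fixed-length overlapping windows
#'
#' Splits each channel into windows of `window_s` seconds advancing by
#' `window_s - overlap_s` seconds. All timing is done in integer samples:
#' with `N` samples per channel, window length `L = window_s * fs` and step
#' `S = (window_s - overlap_s) * fs`, the trial yields
#' `floor((N - L) / S) + 1` windows. Trailing samples that do not fill a
#' final window are discarded, so every window has exactly `L` samples —
#' the fixed-length contract all feature operators rely on. At the
#' reference geometry (60 s stimulus at 256 Hz, 20 s windows, 10 s
#' overlap) a trial yields 5 windows.
#'
#' @param tr a (typically trimmed, see [trim_recovery()]) [trial()].
#' @param window_s window length in seconds (default 20).
#' @param overlap_s overlap between consecutive windows in seconds
#'   (default 10); must satisfy `0 <= overlap_s < window_s`.
#' @return List of `"fear_window"` objects, each with elements `trial_id`,
#'   `window_index` (0-based), `start_s`, `sampling_rate`, `report` and one
#'   numeric vector per sensor (`ECG`, `GSR`, `SKT`).
#' @export
segment_trial <- function(tr, window_s = 20, overlap_s = 10) {
  stopifnot(inherits(tr, "trial"))
  if (window_s <= 0) stop("window_s must be positive")
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("overlap_s must satisfy 0 <= overlap_s < window_s")
  fs <- trial_fs(tr)
  n <- trial_length(tr)
  L <- round(window_s * fs)
  S <- round((window_s - overlap_s) * fs)
  if (n < L)
    stop("trial '", tr$trial_id, "' (", n / fs,
         " s) is shorter than the window length (", window_s, " s)")
  n_win <- (n - L) %/% S + 1L
  lapply(seq_len(n_win) - 1L, function(w) {
    idx <- (w * S + 1L):(w * S + L)
    seg <- lapply(tr$channels, function(ch) ch$values[idx])
    structure(list(trial_id = tr$trial_id, window_index = w,
                   start_s = (w * S) / fs, sampling_rate = fs,
                   report = tr$report,
                   ECG = seg$ECG, GSR = seg$GSR, SKT = seg$SKT),
              class = "fear_window")
  })
}

#' Spectral resolution of a full-window periodogram
#'
#' A single periodogram over a window of `window_s` seconds has bins spaced
#' `1 / window_s` Hz apart; 20 s windows give the 0.05 Hz/bin resolution
#' the sub-Hz autonomic bands require.
#'
#' @param window_s window length in seconds (positive).
#' @return Resolution in Hz per bin.
#' @export
frequency_resolution <- function(window_s) {
  if (!is.numeric(window_s) || length(window_s) != 1 || window_s <= 0)
    stop("window_s must be a positive scalar")
  1 / window_s
}

#' Raw storage requirement of one window
#'
#' Memory needed to buffer one multi-sensor window on an embedded target:
#' `fs * window_s * n_sensors * bits_per_sample / 8` bytes. The reference
#' configuration (256 Hz, 20 s, 3 sensors, 32-bit samples) needs
#' 61440 bytes (60 KB).
#'
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param n_sensors number of sensors buffered.
#' @param bits_per_sample sample width in bits.
#' @return Storage in bytes.
#' @export
storage_bytes <- function(fs, window_s, n_sensors, bits_per_sample) {
  v <- c(fs, window_s, n_sensors, bits_per_sample)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("all arguments must be positive")
  fs * window_s * n_sensors * bits_per_sample / 8
}
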