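# Time- and frequency-domain features: R-peak/IBI extraction, heart-rate
# variability, full-window periodogram band powers, electrodermal
# tonic/phasic decomposition with trough-to-peak SCR detection, and SKT
# moment statistics.

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# non-strict on the left so the end of a flat stretch counts as the trough
local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
}

#' Detect R peaks and build the inter-beat-interval series
#'
#' Works on the preprocessed (band-passed, gain-controlled) ECG, where QRS
#' peaks sit near unit amplitude: candidate peaks are local maxima above
#' half the 99th percentile of the signal; a 0.25 s refractory period is
#' enforced by keeping the larger of two competing candidates. Inter-beat
#' intervals outside (0.25 s, 3 s) are rejected as ectopic/artefactual.
#'
#' @param ecg preprocessed ECG samples (see [preprocess_window()]).
#' @param fs sampling rate in Hz.
#' @param refractory_s minimum spacing between accepted peaks (default 0.25).
#' @return List of class `"ibi_series"` with `r_peak_indices` (1-based
#'   sample positions) and `ibi_values` (seconds). Fewer than 2 peaks is an
#'   error (callers impute and flag such windows).
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.25) {
  if (length(ecg) < 10 * fs)
    stop("R-peak detection needs a window of at least 10 s")
  if (stats::sd(ecg) == 0) stop("constant signal: no beats to detect")
  thr <- 0.5 * stats::quantile(ecg, 0.99, names = FALSE)
  cand <- local_maxima(ecg)
  cand <- cand[ecg[cand] >= thr]
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (ecg[i] > ecg[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  if (length(keep) < 2)
    stop("insufficient beats: fewer than 2 R peaks detected")
  ibi <- diff(keep) / fs
  ok <- ibi > 0.25 & ibi < 3
  structure(list(r_peak_indices = keep, ibi_values = ibi[ok]),
            class = "ibi_series")
}

#' Time-domain heart-rate-variability features
#'
#' Mean inter-beat interval and SDNN (the sample standard deviation of the
#' IBI series), the standard single time-domain variability statistic.
#'
#' @param ibi an `"ibi_series"` from [detect_r_peaks()], or a numeric
#'   vector of intervals in seconds.
#' @return Named list `mean_ibi`, `hrv` (both seconds).
#' @export
ecg_time_features <- function(ibi) {
  v <- if (inherits(ibi, "ibi_series")) ibi$ibi_values else as.numeric(ibi)
  if (length(v) < 3) stop("need at least 3 inter-beat intervals")
  list(mean_ibi = mean(v), hrv = stats::sd(v))
}

#' Spectral mass of a signal in a frequency band
#'
#' Single full-window periodogram (rectangular window, mean removed):
#' with `N` samples the bins are spaced `fs/N` Hz apart, and the band power
#' is the two-sided spectral mass of all bins whose frequency magnitude
#' falls in `[low, high)`. Summed over a partition of `[0, fs/2]` this
#' recovers the signal variance (Parseval).
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz, `0 <= low < high <= fs/2`.
#' @return Band power in squared signal units.
#' @export
band_power <- function(x, fs, low, high) {
  if (low < 0 || high <= low) stop("need 0 <= low < high")
  if (high > fs / 2 + 1e-12) stop("band exceeds the Nyquist frequency")
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^2          # two-sided, sums to var
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # magnitude of signed frequency
  inc <- f >= low & f < high
  if (high >= fs / 2) inc <- inc | abs(f - fs / 2) < 1e-12
  sum(p[inc])
}

#' Frequency-domain features of the inter-beat-interval series
#'
#' The unevenly sampled IBI series (value = interval, time = beat time) is
#' resampled to a uniform grid (default 4 Hz) by cubic spline
#' interpolation, then band powers are read from a full-window
#' periodogram: LF below 0.08 Hz, MF 0.08–0.15 Hz, HF 0.15–0.5 Hz. The MF
#' ratio is `mf / (lf + mf + hf)` and the LF/HF ratio is `lf / hf` (0 with
#' an imputation flag when the denominator is at machine tolerance).
#'
#' @param ibi an `"ibi_series"` or numeric vector of intervals (seconds).
#' @param window_s nominal window length in seconds; the resampled grid
#'   spans `[0, window_s)`.
#' @param resample_hz uniform resampling rate (default 4 Hz).
#' @return Named list `lf`, `mf`, `hf`, `mf_ratio`, `lf_hf_ratio`,
#'   `flagged` (TRUE when degenerate values were imputed), and `uniform`
#'   (the resampled series, reused for detrended fluctuation analysis).
#' @export
ibi_spectral_features <- function(ibi, window_s, resample_hz = 4) {
  v <- if (inherits(ibi, "ibi_series")) ibi$ibi_values else as.numeric(ibi)
  if (length(v) < 4) stop("need at least 4 inter-beat intervals")
  beat_t <- cumsum(v)
  grid <- seq(0, window_s - 1 / resample_hz, by = 1 / resample_hz)
  uniform <- stats::spline(beat_t, v, xout = grid, method = "natural")$y
  lf <- band_power(uniform, resample_hz, 0, 0.08)
  mf <- band_power(uniform, resample_hz, 0.08, 0.15)
  hf <- band_power(uniform, resample_hz, 0.15, 0.5)
  tot <- lf + mf + hf
  flagged <- FALSE
  if (tot < .Machine$double.eps) {
    mf_ratio <- 0; flagged <- TRUE
  } else mf_ratio <- mf / tot
  if (hf < .Machine$double.eps) {
    lf_hf <- 0; flagged <- TRUE
  } else lf_hf <- lf / hf
  list(lf = lf, mf = mf, hf = hf, mf_ratio = mf_ratio, lf_hf_ratio = lf_hf,
       flagged = flagged, uniform = uniform)
}

#' Tonic/phasic decomposition of a GSR window
#'
#' The tonic (skin-conductance level) component is a centered moving median
#' (default 4 s span, shrinking to the valid range at the edges); the
#' phasic component is the residual, so `tonic + phasic` reconstructs the
#' input exactly.
#'
#' @param gsr preprocessed GSR samples (µS).
#' @param fs sampling rate in Hz.
#' @param median_window_s moving-median span in seconds.
#' @return Named list `tonic`, `phasic`.
#' @export
gsr_decompose <- function(gsr, fs, median_window_s = 4) {
  k <- round(median_window_s * fs)
  if (k %% 2 == 0) k <- k + 1L
  if (length(gsr) <= k)
    stop("window shorter than the tonic median span")
  tonic <- as.numeric(stats::runmed(gsr, k, endrule = "median"))
  list(tonic = tonic, phasic = gsr - tonic)
}

#' Trough-to-peak detection of skin-conductance responses
#'
#' Each local maximum of the phasic signal is paired with the nearest
#' preceding local minimum; the pair is kept as an SCR event when the
#' trough-to-peak amplitude reaches `amp_threshold`. Amplitude is
#' `peak - trough` (µS) and rise time is the trough-to-peak interval in
#' seconds.
#'
#' @param phasic phasic GSR samples from [gsr_decompose()].
#' @param fs sampling rate in Hz.
#' @param amp_threshold minimum amplitude in µS (default 0.01).
#' @return `data.frame` with columns `onset_index`, `peak_index` (1-based),
#'   `amplitude`, `rise_time`, ordered by onset; zero rows when no event
#'   qualifies.
#' @export
detect_scrs <- function(phasic, fs, amp_threshold = 0.01) {
  peaks <- local_maxima(phasic)
  troughs <- local_minima(phasic)
  out <- list()
  for (p in peaks) {
    prior <- troughs[troughs < p]
    onset <- if (length(prior)) prior[length(prior)] else 1L
    amp <- phasic[p] - phasic[onset]
    if (amp >= amp_threshold)
      out[[length(out) + 1L]] <- data.frame(
        onset_index = onset, peak_index = p, amplitude = amp,
        rise_time = (p - onset) / fs)
  }
  if (!length(out))
    return(data.frame(onset_index = integer(0), peak_index = integer(0),
                      amplitude = numeric(0), rise_time = numeric(0)))
  do.call(rbind, out)
}

#' Linear GSR feature block
#'
#' Time-domain block (default `"iqr"` profile, 6 values): SCR count, mean
#' SCR amplitude, mean SCR rise time, raw mean, raw standard deviation and
#' the interquartile range (linear-interpolation quantiles). The
#' `"separate"` profile emits Q1 and Q3 instead of their difference.
#' Frequency block (3 values): tonic-component power in `[0, 0.05)` Hz,
#' phasic-component power in `[0.05, 1.5)` Hz, and the low-band ratio
#' `tonic low-band power / (tonic low + phasic band)` (0, flagged, when the
#' total is at machine tolerance). With no detected events the amplitude
#' and rise-time means are 0.
#'
#' @param gsr preprocessed GSR samples (µS).
#' @param tonic,phasic components from [gsr_decompose()].
#' @param events SCR table from [detect_scrs()].
#' @param fs sampling rate in Hz.
#' @param quartiles `"iqr"` or `"separate"`.
#' @return Named list of 9 (or 10) feature values plus `flagged`.
#' @export
gsr_linear_features <- function(gsr, tonic, phasic, events, fs,
                                quartiles = c("iqr", "separate")) {
  quartiles <- match.arg(quartiles)
  qs <- stats::quantile(gsr, c(0.25, 0.75), names = FALSE, type = 7)
  p_tonic <- band_power(tonic, fs, 0, 0.05)
  p_phasic <- band_power(phasic, fs, 0.05, min(1.5, fs / 2))
  tot <- p_tonic + p_phasic
  flagged <- FALSE
  if (tot < .Machine$double.eps) {
    ratio_low <- 0; flagged <- TRUE
  } else ratio_low <- p_tonic / tot
  disp <- if (quartiles == "iqr") list(iqr = qs[2] - qs[1])
          else list(q1 = qs[1], q3 = qs[2])
  c(list(n_scr = nrow(events),
         scr_amp_mean = if (nrow(events)) mean(events$amplitude) else 0,
         scr_rise_mean = if (nrow(events)) mean(events$rise_time) else 0,
         mean = mean(gsr), sd = stats::sd(gsr)),
    disp,
    list(psd_tonic_low = p_tonic, psd_phasic_band = p_phasic,
         psd_ratio_low = ratio_low, flagged = flagged))
}

#' Skin-temperature feature block
#'
#' Mean, sample standard deviation, skewness (standardized third central
#' moment) and Pearson kurtosis (standardized fourth central moment, not
#' excess), plus band powers in `[0, 0.1)` and `[0.1, 0.2)` Hz. A
#' zero-variance window yields flagged zero moments.
#'
#' @param skt preprocessed SKT samples (°C).
#' @param fs sampling rate in Hz.
#' @return Named list `mean`, `sd`, `skewness`, `kurtosis`, `psd_000_010`,
#'   `psd_010_020`, `flagged`.
#' @export
skt_features <- function(skt, fs) {
  if (!length(skt)) stop("empty window")
  m <- mean(skt)
  s <- stats::sd(skt)
  flagged <- FALSE
  if (!is.finite(s) || s == 0) {
    skew <- kurt <- 0
    s <- 0
    flagged <- TRUE
  } else {
    d <- skt - m
    m2 <- mean(d^2)
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  list(mean = m, sd = s, skewness = skew, kurtosis = kurt,
       psd_000_010 = band_power(skt, fs, 0, 0.1),
       psd_010_020 = band_power(skt, fs, 0.1, 0.2),
       flagged = flagged)
}
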