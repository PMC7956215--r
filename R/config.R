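#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in a single flat list.
#' Call with no arguments for the defaults; pass `key = value` pairs to
#' override. Unknown keys are rejected, which catches typos early.
#'
#' Key groups (defaults in parentheses):
#' \describe{
#'   \item{ECG filtering}{`ecg.highpass_hz` (0.5), `ecg.lowpass_hz` (40),
#'     `ecg.taps` (255): band edges in Hz and tap count of the
#'     Hamming-windowed linear-phase FIR cascade.}
#'   \item{GSR/SKT filtering}{`gsr.lowpass_hz` (2), `skt.lowpass_hz` (1),
#'     `lp.taps` (129).}
#'   \item{Automatic gain control}{`agc.window_s` (1.5) moving-maximum
#'     envelope span — longer than the longest expected beat interval but
#'     shorter than two of them, so neighboring beats of different height
#'     are normalized independently; `agc.smooth_s` (0.5) moving-average
#'     smoothing,
#'     `agc.floor_frac` (0.05) envelope floor as a fraction of the global
#'     absolute maximum.}
#'   \item{Electrodermal}{`gsr.median_s` (4) moving-median span for the
#'     tonic component, `scr.amp_threshold` (0.01 µS) minimum
#'     trough-to-peak amplitude of a skin-conductance response,
#'     `gsr.quartiles` ("iqr"): `"iqr"` emits a single interquartile-range
#'     dispersion column (48-feature layout), `"separate"` emits Q1 and Q3
#'     (49 columns).}
#'   \item{Heart-rate variability}{`ibi.resample_hz` (4) uniform grid for
#'     the interpolated inter-beat-interval series,
#'     `ecg.band_source` ("waveform"): whether the four 0–0.4 Hz ECG band
#'     powers are taken on the preprocessed waveform or on the resampled
#'     heart-rate series (`"ibi"`).}
#'   \item{Phase-space embedding}{`embed.max_lag` (32 samples at the
#'     decimated rate), `embed.max_dim` (6), `embed.decimate_hz` (32):
#'     ECG and GSR are decimated to this rate before embedding, recurrence
#'     analysis, multiscale entropy and detrended fluctuation analysis.}
#'   \item{Recurrence analysis}{`rqa.e_frac` (0.10) recurrence threshold as
#'     a fraction of the phase-space diameter, `rqa.e_mode` ("mean"): the
#'     diameter is the mean (or `"max"`) pairwise distance, `rqa.theiler`
#'     (1), `rqa.l_min` (2), `rqa.v_min` (2).}
#'   \item{Entropy / scaling}{`mse.scales` (5), `mse.m` (2), `mse.r_frac`
#'     (0.2 of the scale-1 standard deviation), `dfa.min_box` (4),
#'     `dfa.max_box_frac` (0.25).}
#'   \item{Labeling}{`label.midpoint` (5): SAM rating at which each
#'     pleasure-arousal-dominance scale is split.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `"fear_config"`.
#' @examples
#' cfg <- fear_config(gsr.lowpass_hz = 1.5)
#' cfg$gsr.lowpass_hz
#' @export
fear_config <- function(...) {
  defaults <- list(
    ecg.highpass_hz = 0.5,
    ecg.lowpass_hz  = 40,
    ecg.taps        = 255,
    gsr.lowpass_hz  = 2,
    skt.lowpass_hz  = 1,
    lp.taps         = 129,
    agc.window_s    = 1.5,
    agc.smooth_s    = 0.5,
    agc.floor_frac  = 0.05,
    gsr.median_s    = 4,
    scr.amp_threshold = 0.01,
    gsr.quartiles   = "iqr",
    ibi.resample_hz = 4,
    ecg.band_source = "waveform",
    embed.max_lag   = 32,
    embed.max_dim   = 6,
    embed.decimate_hz = 32,
    rqa.e_frac      = 0.10,
    rqa.e_mode      = "mean",
    rqa.theiler     = 1,
    rqa.l_min       = 2,
    rqa.v_min       = 2,
    mse.scales      = 5,
    mse.m           = 2,
    mse.r_frac      = 0.2,
    dfa.min_box     = 4,
    dfa.max_box_frac = 0.25,
    label.midpoint  = 5
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  stopifnot(defaults$gsr.quartiles %in% c("iqr", "separate"),
            defaults$rqa.e_mode %in% c("mean", "max"),
            defaults$ecg.band_source %in% c("waveform", "ibi"))
  structure(defaults, class = "fear_config")
}

#' @export
print.fear_config <- function(x, ...) {
  cat("fear pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

as_fear_config <- function(cfg) {
  if (is.null(cfg)) return(fear_config())
  if (!inherits(cfg, "fear_config")) stop("`cfg` must come from fear_config()")
  cfg
}
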