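#' Ordered feature-name registry
#'
#' The classifier consumes a fixed, ordered layout of named features:
#' 25 ECG, 17 GSR and 6 SKT columns (48 in total) in the default
#' `"iqr"` profile. The alternative `"separate"` profile replaces the single
#' GSR interquartile-range column with the first and third quartiles,
#' giving 49 columns. Downstream code must never rely on positional
#' indexing outside this registry.
#'
#' @param quartiles `"iqr"` (default, 48 names) or `"separate"` (49 names).
#' @param sensor optionally restrict to one of `"ecg"`, `"gsr"`, `"skt"`.
#' @return Character vector of feature names, in canonical column order.
#' @examples
#' length(feature_names())        # 48
#' length(feature_names("separate"))  # 49
#' @export
feature_names <- function(quartiles = c("iqr", "separate"),
                          sensor = NULL) {
  quartiles <- match.arg(quartiles)
  ecg <- c(
    "ecg.mean_ibi", "ecg.sdnn",
    "ecg.psd_000_010", "ecg.psd_010_020", "ecg.psd_020_030", "ecg.psd_030_040",
    "ecg.ibi_lf", "ecg.ibi_mf", "ecg.ibi_hf",
    "ecg.ibi_mf_ratio", "ecg.ibi_lf_hf_ratio",
    paste0("ecg.mse_", 1:5),
    "ecg.dfa_raw", "ecg.dfa_ibi",
    "ecg.rqa_rr", "ecg.rqa_det", "ecg.rqa_lam", "ecg.rqa_lmax",
    "ecg.rqa_entr", "ecg.rqa_tt",
    "ecg.corr_dim"
  )
  gsr_disp <- if (quartiles == "iqr") "gsr.iqr" else c("gsr.q1", "gsr.q3")
  gsr <- c(
    "gsr.n_scr", "gsr.scr_amp_mean", "gsr.scr_rise_mean",
    "gsr.mean", "gsr.sd", gsr_disp,
    "gsr.psd_tonic_low", "gsr.psd_phasic_band", "gsr.psd_ratio_low",
    "gsr.dfa",
    "gsr.rqa_rr", "gsr.rqa_det", "gsr.rqa_lam", "gsr.rqa_lmax",
    "gsr.rqa_entr", "gsr.rqa_tt",
    "gsr.corr_dim"
  )
  skt <- c("skt.mean", "skt.sd", "skt.skewness", "skt.kurtosis",
           "skt.psd_000_010", "skt.psd_010_020")
  out <- c(ecg, gsr, skt)
  if (!is.null(sensor)) {
    sensor <- match.arg(sensor, c("ecg", "gsr", "skt"))
    out <- out[startsWith(out, paste0(sensor, "."))]
  }
  out
}
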