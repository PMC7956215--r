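# Window-level 48-feature extraction and the session -> feature-table
# pipeline.

decimate_signal <- function(x, fs, target_hz, taps = 129) {
  if (target_hz >= fs) return(list(values = x, fs = fs))
  q <- round(fs / target_hz)
  new_fs <- fs / q
  y <- apply_fir(x, fir_taps("lowpass", 0.45 * new_fs, fs, taps))
  list(values = y[seq(1, length(y), by = q)], fs = new_fs)
}

safe_block <- function(expr, default) {
  tryCatch(suppressWarnings(expr), error = function(e) default)
}

nonlinear_block <- function(x, fs, cfg, mse = FALSE) {
  # shared RQA / correlation-dimension / DFA (+ optional multiscale
  # entropy) block computed on the decimated series
  dec <- decimate_signal(x, fs, cfg$embed.decimate_hz)
  xs <- dec$values
  zero_rqa <- list(recurrence_rate = 0, determinism = 0, laminarity = 0,
                   longest_diagonal = 0, diagonal_entropy = 0,
                   trapping_time = 0)
  out <- list(rqa = zero_rqa, corr_dim = 0, dfa = 0,
              mse = rep(0, cfg$mse.scales), flagged = FALSE)
  emb <- safe_block({
    T <- estimate_delay(xs, cfg$embed.max_lag)
    M <- estimate_dimension(xs, T, cfg$embed.max_dim)
    embed_series(xs, T, M)
  }, NULL)
  if (is.null(emb)) {
    out$flagged <- TRUE
  } else {
    rp <- safe_block(recurrence_matrix(emb, cfg$rqa.e_frac, cfg$rqa.e_mode),
                     NULL)
    if (is.null(rp)) out$flagged <- TRUE
    else out$rqa <- rqa_measures(rp, cfg$rqa.l_min, cfg$rqa.v_min,
                                 cfg$rqa.theiler)
    d2 <- correlation_dimension(emb)
    out$corr_dim <- d2$d2
    out$flagged <- out$flagged || d2$flagged
  }
  df <- safe_block(dfa_alpha(xs, cfg$dfa.min_box, cfg$dfa.max_box_frac),
                   list(alpha = 0, flagged = TRUE))
  out$dfa <- df$alpha
  out$flagged <- out$flagged || df$flagged
  if (mse) {
    ms <- safe_block(multiscale_entropy(xs, cfg$mse.scales, cfg$mse.m,
                                        cfg$mse.r_frac),
                     list(values = rep(0, cfg$mse.scales), flagged = TRUE))
    out$mse <- ms$values
    out$flagged <- out$flagged || ms$flagged
  }
  out
}

#' Extract the full feature vector of one window
#'
#' Runs the complete per-window pipeline: denoising
#' ([preprocess_window()]), R-peak/IBI extraction, time-domain and spectral
#' heart-rate-variability features, tonic/phasic electrodermal
#' decomposition with trough-to-peak SCR detection, skin-temperature
#' moments and band powers, and the non-linear block (recurrence
#' quantification, correlation dimension, multiscale entropy, detrended
#' fluctuation analysis) on ECG and GSR decimated to
#' `embed.decimate_hz`. Degenerate sub-computations (too few beats, zero
#' variance, collapsed geometry) are imputed as zeros and recorded in the
#' `"flags"` attribute instead of producing missing values, so the
#' fixed-geometry window layout survives.
#'
#' @param win a `"fear_window"` from [segment_trial()].
#' @param cfg a [fear_config()].
#' @param preprocessed set to `TRUE` when `win` already went through
#'   [preprocess_window()].
#' @return Named numeric vector ordered as [feature_names()], with a
#'   character `"flags"` attribute naming imputed feature groups.
#' @export
extract_features <- function(win, cfg = fear_config(), preprocessed = FALSE) {
  cfg <- as_fear_config(cfg)
  stopifnot(inherits(win, "fear_window"))
  fs <- win$sampling_rate
  if (!preprocessed) win <- preprocess_window(win, cfg)
  window_s <- length(win$ECG) / fs
  flags <- character(0)
  out <- list()

  ## ---- ECG ----
  ibi <- safe_block(detect_r_peaks(win$ECG, fs), NULL)
  if (is.null(ibi) || length(ibi$ibi_values) < 3) {
    out$ecg.mean_ibi <- 0; out$ecg.sdnn <- 0
    flags <- c(flags, "ecg.ibi")
    ibi_ok <- FALSE
  } else {
    tf <- ecg_time_features(ibi)
    out$ecg.mean_ibi <- tf$mean_ibi
    out$ecg.sdnn <- tf$hrv
    ibi_ok <- TRUE
  }
  ibi_spec <- NULL
  if (ibi_ok && length(ibi$ibi_values) >= 4)
    ibi_spec <- safe_block(
      ibi_spectral_features(ibi, window_s, cfg$ibi.resample_hz), NULL)
  ecg_bands <- list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3), c(0.3, 0.4))
  band_src <- if (cfg$ecg.band_source == "ibi" && !is.null(ibi_spec))
    list(x = ibi_spec$uniform, fs = cfg$ibi.resample_hz)
  else list(x = win$ECG, fs = fs)
  bp <- vapply(ecg_bands, function(b)
    band_power(band_src$x, band_src$fs, b[1], b[2]), numeric(1))
  out$ecg.psd_000_010 <- bp[1]; out$ecg.psd_010_020 <- bp[2]
  out$ecg.psd_020_030 <- bp[3]; out$ecg.psd_030_040 <- bp[4]
  if (is.null(ibi_spec)) {
    out$ecg.ibi_lf <- out$ecg.ibi_mf <- out$ecg.ibi_hf <- 0
    out$ecg.ibi_mf_ratio <- out$ecg.ibi_lf_hf_ratio <- 0
    flags <- c(flags, "ecg.ibi_spectrum")
  } else {
    out$ecg.ibi_lf <- ibi_spec$lf; out$ecg.ibi_mf <- ibi_spec$mf
    out$ecg.ibi_hf <- ibi_spec$hf
    out$ecg.ibi_mf_ratio <- ibi_spec$mf_ratio
    out$ecg.ibi_lf_hf_ratio <- ibi_spec$lf_hf_ratio
    if (ibi_spec$flagged) flags <- c(flags, "ecg.ibi_ratios")
  }
  nl_ecg <- nonlinear_block(win$ECG, fs, cfg, mse = TRUE)
  for (s in seq_len(cfg$mse.scales))
    out[[paste0("ecg.mse_", s)]] <- nl_ecg$mse[s]
  out$ecg.dfa_raw <- nl_ecg$dfa
  if (is.null(ibi_spec)) {
    out$ecg.dfa_ibi <- 0
    flags <- c(flags, "ecg.dfa_ibi")
  } else {
    di <- safe_block(dfa_alpha(ibi_spec$uniform, cfg$dfa.min_box,
                               cfg$dfa.max_box_frac),
                     list(alpha = 0, flagged = TRUE))
    out$ecg.dfa_ibi <- di$alpha
    if (di$flagged) flags <- c(flags, "ecg.dfa_ibi")
  }
  out$ecg.rqa_rr <- nl_ecg$rqa$recurrence_rate
  out$ecg.rqa_det <- nl_ecg$rqa$determinism
  out$ecg.rqa_lam <- nl_ecg$rqa$laminarity
  out$ecg.rqa_lmax <- nl_ecg$rqa$longest_diagonal
  out$ecg.rqa_entr <- nl_ecg$rqa$diagonal_entropy
  out$ecg.rqa_tt <- nl_ecg$rqa$trapping_time
  out$ecg.corr_dim <- nl_ecg$corr_dim
  if (nl_ecg$flagged) flags <- c(flags, "ecg.nonlinear")

  ## ---- GSR ----
  dec <- gsr_decompose(win$GSR, fs, cfg$gsr.median_s)
  events <- detect_scrs(dec$phasic, fs, cfg$scr.amp_threshold)
  gl <- gsr_linear_features(win$GSR, dec$tonic, dec$phasic, events, fs,
                            cfg$gsr.quartiles)
  if (isTRUE(gl$flagged)) flags <- c(flags, "gsr.spectrum")
  gl$flagged <- NULL
  for (nm in names(gl)) out[[paste0("gsr.", nm)]] <- gl[[nm]]
  nl_gsr <- nonlinear_block(win$GSR, fs, cfg, mse = FALSE)
  out$gsr.dfa <- nl_gsr$dfa
  out$gsr.rqa_rr <- nl_gsr$rqa$recurrence_rate
  out$gsr.rqa_det <- nl_gsr$rqa$determinism
  out$gsr.rqa_lam <- nl_gsr$rqa$laminarity
  out$gsr.rqa_lmax <- nl_gsr$rqa$longest_diagonal
  out$gsr.rqa_entr <- nl_gsr$rqa$diagonal_entropy
  out$gsr.rqa_tt <- nl_gsr$rqa$trapping_time
  out$gsr.corr_dim <- nl_gsr$corr_dim
  if (nl_gsr$flagged) flags <- c(flags, "gsr.nonlinear")

  ## ---- SKT ----
  sf <- skt_features(win$SKT, fs)
  if (isTRUE(sf$flagged)) flags <- c(flags, "skt.moments")
  sf$flagged <- NULL
  for (nm in names(sf)) out[[paste0("skt.", nm)]] <- sf[[nm]]

  want <- feature_names(cfg$gsr.quartiles)
  vec <- unlist(out)[want]
  stopifnot(!anyNA(vec))
  attr(vec, "flags") <- unique(flags)
  vec
}

#' Build a feature table from sessions
#'
#' End-to-end extraction: each trial is recovery-trimmed, segmented into
#' fixed-length overlapping windows, denoised and reduced to the ordered
#' feature vector of [feature_names()]; the trial's self-report is
#' binarized into the fear label every window inherits.
#'
#' @param sessions a [session()] or list of sessions.
#' @param window_s,overlap_s segmentation parameters (defaults 20 s / 10 s).
#' @param pre_trim_s,post_trim_s recovery trimming; `NULL` (default) uses
#'   each trial's recorded padding.
#' @param cfg a [fear_config()].
#' @param verbose print one line per session.
#' @return Feature-table `data.frame` (`subject_id`, `trial_id`,
#'   `window_index`, feature columns, `fear_label`).
#' @export
extract_feature_table <- function(sessions, window_s = 20, overlap_s = 10,
                                  pre_trim_s = NULL, post_trim_s = NULL,
                                  cfg = fear_config(), verbose = FALSE) {
  cfg <- as_fear_config(cfg)
  if (inherits(sessions, "session")) sessions <- list(sessions)
  rows <- list()
  for (ses in sessions) {
    if (verbose)
      message("extracting subject ", ses$subject_id, " (",
              length(ses$trials), " trials)")
    for (tr in ses$trials) {
      trm <- trim_recovery(tr,
                           if (is.null(pre_trim_s)) tr$pre_recovery_s
                           else pre_trim_s,
                           if (is.null(post_trim_s)) tr$post_recovery_s
                           else post_trim_s)
      label <- binarize_pad(trm$report, midpoint = cfg$label.midpoint)
      for (win in segment_trial(trm, window_s, overlap_s)) {
        fv <- extract_features(win, cfg)
        rows[[length(rows) + 1L]] <- c(
          list(subject_id = ses$subject_id, trial_id = tr$trial_id,
               window_index = win$window_index),
          as.list(unclass(fv)), list(fear_label = label))
      }
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  validate_feature_table(tab)
  tab
}
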