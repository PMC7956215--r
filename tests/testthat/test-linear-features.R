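fs <- 256

test_that("R-peak detection recovers generator ground truth", {
  # 60 bpm, no variability: exactly periodic beats, 20 in 20 s
  ecg <- synth_ecg(fs, 20, 60, 0, seed = 1, snr_db = 40)
  win <- structure(list(trial_id = "T", window_index = 0L, start_s = 0,
                        sampling_rate = fs, report = self_report(5, 5, 5),
                        ECG = ecg$values, GSR = rep(5, 20 * fs),
                        SKT = rep(33, 20 * fs)), class = "fear_window")
  pre <- preprocess_window(win)
  ibi <- detect_r_peaks(pre$ECG, fs)
  expect_equal(length(ibi$r_peak_indices), length(ecg$r_times))
  expect_equal(mean(ibi$ibi_values), 1.0, tolerance = 1 / fs)
  # matched within 50 ms of the true beat times
  matched <- vapply(ecg$r_times, function(rt)
    min(abs(ibi$r_peak_indices / fs - rt)), numeric(1))
  expect_lt(max(matched), 0.05)

  expect_error(detect_r_peaks(rep(0.3, 20 * fs), fs), "constant")
  expect_error(detect_r_peaks(pre$ECG[1:(5 * fs)], fs), "10 s")
})

test_that("R-peak recall and precision are perfect at 20 dB over seeds", {
  for (seed in 1:5) {
    hr <- c(55, 65, 75, 85, 70)[seed]
    ecg <- synth_ecg(fs, 20, hr, 0.05, seed = seed, snr_db = 20)
    y <- apply_agc(filter_ecg(ecg$values, fs), fs)
    det <- detect_r_peaks(y, fs)$r_peak_indices / fs
    truth <- ecg$r_times
    # drop truth beats whose template center falls outside the window
    truth <- truth[truth > 0.1 & truth < 20 - 0.1]
    hits <- vapply(truth, function(rt) any(abs(det - rt) < 0.05), logical(1))
    false_pos <- vapply(det, function(d)
      !any(abs(truth - d) < 0.05), logical(1))
    expect_true(all(hits), info = paste("seed", seed))
    expect_lte(sum(false_pos), 1)  # at most an edge beat outside truth span
  }
})

test_that("time-domain variability features match direct formulas", {
  expect_equal(ecg_time_features(c(1, 1, 1)), list(mean_ibi = 1, hrv = 0))
  f <- ecg_time_features(c(0.8, 1.2, 0.8, 1.2))
  expect_equal(f$mean_ibi, 1.0)
  expect_equal(f$hrv, sd(c(0.8, 1.2, 0.8, 1.2)))
  expect_equal(f$hrv, 0.2309, tolerance = 1e-3)
  expect_error(ecg_time_features(c(1, 1)), "at least 3")
})

test_that("band powers match a Parseval oracle", {
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 0.15 * t)
  total <- band_power(x, fs, 0, fs / 2)
  expect_gt(band_power(x, fs, 0.1, 0.2) / total, 0.95)
  # mean-removed constant has zero power everywhere
  expect_equal(band_power(rep(3, 1000), fs, 0, 10), 0)
  # partition of [0, Nyquist) sums to the total variance
  set.seed(2)
  y <- rnorm(5120)
  edges <- c(0, 1, 5, 20, 60, fs / 2)
  parts <- sum(vapply(seq_len(length(edges) - 1), function(i)
    band_power(y, fs, edges[i], edges[i + 1]), numeric(1)))
  expect_equal(parts, mean((y - mean(y))^2), tolerance = 0.01)
  expect_error(band_power(y, fs, 0, 200), "Nyquist")
})

test_that("IBI spectral features localize imposed modulation", {
  # constant series: no spectral mass, flagged ratios
  f0 <- ibi_spectral_features(rep(1, 20), 20)
  expect_equal(f0$lf + f0$mf + f0$hf, 0, tolerance = 1e-20)
  expect_true(f0$flagged)
  expect_equal(f0$lf_hf_ratio, 0)

  # 0.1 Hz modulation lands in the mid band
  n <- 60
  beat_t <- cumsum(rep(1, n))
  ibi <- 1 + 0.1 * sin(2 * pi * 0.1 * beat_t)
  fm <- ibi_spectral_features(ibi, 60)
  expect_gt(fm$mf_ratio, 0.8)

  # 0.25 Hz modulation lands in the high band
  ibi2 <- 1 + 0.1 * sin(2 * pi * 0.25 * beat_t)
  fh <- ibi_spectral_features(ibi2, 60)
  expect_gt(fh$hf / (fh$lf + fh$mf + fh$hf), 0.8)
  expect_error(ibi_spectral_features(c(1, 1, 1), 20), "at least 4")
})

test_that("tonic/phasic decomposition reconstructs exactly", {
  # constant input: all tonic
  const <- rep(5, 10 * fs)
  d <- gsr_decompose(const, fs)
  expect_equal(d$tonic, const)
  expect_equal(d$phasic, rep(0, length(const)))

  # ramp goes to tonic, a 2 s bump survives in phasic
  t <- (0:(20 * fs - 1)) / fs
  ramp <- 5 + 0.02 * t
  bump <- 0.5 * exp(-(t - 10)^2 / (2 * 0.5^2))
  d2 <- gsr_decompose(ramp + bump, fs)
  expect_gt(max(d2$phasic), 0.8 * 0.5)
  expect_lt(max(abs(d2$tonic - ramp)), 0.15)

  # reconstruction is an identity for arbitrary input
  set.seed(3)
  x <- cumsum(rnorm(5 * fs))
  d3 <- gsr_decompose(x, fs, 2)
  expect_equal(d3$tonic + d3$phasic, x, tolerance = 1e-14)
})

test_that("trough-to-peak SCR detection recovers injected events", {
  expect_equal(nrow(detect_scrs(rep(0, 5120), fs)), 0)

  t <- (0:(60 * fs - 1)) / fs
  # one injected pulse of amplitude 0.5 is itself a phasic signal
  pulse <- fearsense:::bateman_pulse(pmax(t - 20, 0), 0.5, tau_d = 4) *
    (t >= 20)
  ev <- detect_scrs(pulse, fs, 0.05)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 0.5, tolerance = 0.10)
  t_peak <- log(4 / 0.75) * 0.75 * 4 / (4 - 0.75)
  expect_lt(abs(ev$rise_time - t_peak), 0.2)

  # two pulses 8 s apart, ordered
  pulse2 <- pulse + fearsense:::bateman_pulse(pmax(t - 28, 0), 0.3,
                                              tau_d = 3) * (t >= 28)
  ev2 <- detect_scrs(pulse2, fs, 0.05)
  expect_equal(nrow(ev2), 2)
  expect_true(all(diff(ev2$peak_index) > 0))
  expect_lt(abs(ev2$peak_index[2] - ev2$peak_index[1]) / fs - 8, 1)
})

test_that("SCR count is monotone non-increasing in the threshold", {
  g <- synth_gsr(fs, 60, tonic = 5, drift = 0.1, scr_rate = 6, seed = 5)
  phasic <- gsr_decompose(g$values, fs)$phasic
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 1),
                   function(th) nrow(detect_scrs(phasic, fs, th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("GSR linear block matches direct statistics", {
  const <- rep(5, 20 * fs)
  d <- gsr_decompose(const, fs)
  ev <- detect_scrs(d$phasic, fs)
  gl <- gsr_linear_features(const, d$tonic, d$phasic, ev, fs)
  expect_equal(gl$n_scr, 0)
  expect_equal(gl$scr_amp_mean, 0)
  expect_equal(gl$mean, 5)
  expect_equal(gl$sd, 0)
  expect_equal(gl$iqr, 0)
  expect_equal(gl$psd_ratio_low, 0)   # flagged: no spectral mass at all
  expect_true(gl$flagged)

  # quantile dispersion against a direct sort-and-interpolate oracle
  manual_q <- function(y, p) {
    s <- sort(y); h <- (length(s) - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[pmin(floor(h) + 1, length(s))] -
                                      s[floor(h)])
  }
  set.seed(8)
  y <- rep(as.numeric(1:100), length.out = 20 * fs) + rnorm(20 * fs, 0, 5)
  d2 <- gsr_decompose(y, fs)
  ev2 <- detect_scrs(d2$phasic, fs)
  gl2 <- gsr_linear_features(y, d2$tonic, d2$phasic, ev2, fs)
  expect_equal(gl2$iqr, manual_q(y, 0.75) - manual_q(y, 0.25))
  gl3 <- gsr_linear_features(y, d2$tonic, d2$phasic, ev2, fs,
                             quartiles = "separate")
  expect_equal(gl3$q1, manual_q(y, 0.25))
  expect_equal(gl3$q3, manual_q(y, 0.75))
})

test_that("SKT features match moment oracles", {
  f0 <- skt_features(rep(33, 1000), fs)
  expect_equal(unlist(f0[c("mean", "sd", "skewness", "kurtosis")]),
               c(mean = 33, sd = 0, skewness = 0, kurtosis = 0))
  expect_true(f0$flagged)

  set.seed(6)
  x <- rnorm(20000, 33, 0.5)
  f <- skt_features(x, fs)
  expect_equal(f$mean, mean(x))
  expect_equal(f$sd, sd(x))
  expect_lt(abs(f$skewness), 0.1)
  expect_equal(f$kurtosis, 3, tolerance = 0.1)
  # cross-check against e1071 moment conventions
  expect_equal(f$skewness, e1071::skewness(x, type = 1), tolerance = 1e-10)
  expect_equal(f$kurtosis - 3, e1071::kurtosis(x, type = 1),
               tolerance = 1e-10)

  # a 0.15 Hz oscillation puts its mass in the upper band
  t <- (0:(20 * fs - 1)) / fs
  osc <- 33 + 0.2 * sin(2 * pi * 0.15 * t)
  fo <- skt_features(osc, fs)
  expect_gt(fo$psd_010_020, fo$psd_000_010)
})
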