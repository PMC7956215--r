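fs <- 256

test_that("ECG generator honors rate, variability and determinism", {
  # 60 bpm with zero variability: exactly periodic, 20 beats in 20 s
  e <- synth_ecg(fs, 20, 60, 0, seed = 30)
  expect_equal(length(e$r_times), 20)
  expect_equal(diff(e$r_times), rep(1, 19), tolerance = 1e-12)

  # same seed, same samples; different seed differs
  e2 <- synth_ecg(fs, 20, 60, 0.05, seed = 31)
  e3 <- synth_ecg(fs, 20, 60, 0.05, seed = 31)
  expect_identical(e2$values, e3$values)
  expect_false(identical(e2$values,
                         synth_ecg(fs, 20, 60, 0.05, seed = 32)$values))

  # empirical beat-to-beat SD approaches the requested value over 5 min
  rr <- unlist(lapply(1:4, function(s)
    diff(synth_ecg(fs, 300, 60, 0.05, seed = 40 + s)$r_times)))
  expect_equal(sd(rr), 0.05, tolerance = 0.15)
  expect_error(synth_ecg(fs, 20, 200, 0, seed = 1), "\\[45, 120\\]")
})

test_that("GSR generator produces Poisson-timed recoverable SCRs", {
  g0 <- synth_gsr(fs, 60, tonic = 5, scr_rate = 0, seed = 33)
  expect_equal(nrow(g0$events), 0)

  # rate 3/min over 10 min: mean count over seeds inside the 95% interval
  # for a mean of a Poisson(30) sample
  counts <- vapply(1:10, function(s)
    nrow(synth_gsr(fs, 600, tonic = 5, scr_rate = 3, seed = s)$events),
    numeric(1))
  half <- 1.96 * sqrt(30 / 10)
  expect_gte(mean(counts), 30 - half)
  expect_lte(mean(counts), 30 + half)

  expect_identical(synth_gsr(fs, 30, 5, scr_rate = 2, seed = 35)$values,
                   synth_gsr(fs, 30, 5, scr_rate = 2, seed = 35)$values)
  expect_error(synth_gsr(fs, 30, tonic = -1, seed = 1), "non-negative")
})

test_that("injected SCR amplitudes survive the detection pipeline", {
  # end-to-end: generator -> low-pass -> decimate -> tonic/phasic split ->
  # trough-to-peak events. Amplitude fidelity is judged on isolated events
  # (no neighbor within 20 s): overlapping responses ride on each other's
  # decay, so their trough-to-peak amplitude is genuinely smaller than the
  # injected kernel amplitude. The tonic median span (80 s) is sized for
  # these 5-minute records so it does not absorb slow-decay responses.
  errs <- fearsense:::scr_recovery_errors(seeds = 1:6, duration_s = 300,
                                          scr_rate = 1.5, snr_db = 20)
  expect_gt(length(errs), 10)
  expect_lt(mean(errs), 0.15)
})

test_that("SKT generator drifts and stays band-limited", {
  s0 <- synth_skt(fs, 60, 33, 0, seed = 36, noise_sd = 0)
  expect_equal(s0, rep(33, 60 * fs))

  s1 <- synth_skt(fs, 600, 33, -0.1, seed = 37, noise_sd = 0)
  expect_equal(s1[length(s1)] - s1[1], -1.0, tolerance = 0.05 / 1)

  s2 <- synth_skt(fs, 60, 33, 0, seed = 38, noise_sd = 0.05)
  hi <- band_power(s2, fs, 0.5, fs / 2)
  tot <- band_power(s2, fs, 0, fs / 2)
  expect_lt(hi / tot, 0.01)
  expect_error(synth_skt(fs, 60, 20, 0, seed = 1), "\\[25, 40\\]")
})

test_that("session structure matches the recording protocol", {
  out <- small_session()
  ses <- out$session
  expect_length(ses$trials, 2)
  for (tr in ses$trials) {
    expect_equal(fearsense:::trial_duration(tr), 120)   # 30 + 60 + 30
    expect_equal(tr$pre_recovery_s, 30)
    expect_equal(tr$post_recovery_s, 30)
    expect_equal(fearsense:::trial_fs(tr), 256)
  }
  # a fear fraction of 0.2 over 20 trials fixes 4 fear trials
  p <- subject_profile()
  big <- synth_session(p, condition_effect(), "SX", n_trials = 20,
                       fear_fraction = 0.2, seed = 39, stimulus_s = 10,
                       recovery_s = 2)
  expect_equal(sum(big$truth$condition == "fear"), 4)

  # noiseless reports map conditions onto labels exactly
  p0 <- subject_profile(report_noise_sd = 0)
  s0 <- synth_session(p0, condition_effect(), "SY", n_trials = 6,
                      fear_fraction = 0.5, seed = 41, stimulus_s = 10,
                      recovery_s = 2)
  labs <- vapply(s0$session$trials, function(tr) binarize_pad(tr$report),
                 integer(1))
  expect_equal(unname(labs),
               as.integer(s0$truth$condition == "fear"))
})

test_that("fear trials carry the imposed autonomic signature", {
  p <- subject_profile(baseline_hr = 70, report_noise_sd = 0)
  eff <- condition_effect(hr_delta = 15, scr_rate_factor = 3,
                          skt_delta = -0.5)
  out <- synth_session(p, eff, "SZ", n_trials = 6, fear_fraction = 0.5,
                       seed = 42)
  truth <- out$truth
  hr_stim <- vapply(seq_len(6), function(i) {
    rt <- truth$r_times[[i]]
    sum(rt > 30 & rt < 90) # beats in the stimulus minute
  }, numeric(1))
  fear <- truth$condition == "fear"
  expect_gt(mean(hr_stim[fear]), mean(hr_stim[!fear]) + 10)
  skt_drop <- vapply(out$session$trials, function(tr) {
    v <- tr$channels$SKT$values
    mean(v[(60 * fs):(85 * fs)]) - mean(v[1:(25 * fs)])
  }, numeric(1))
  expect_lt(mean(skt_drop[fear]), mean(skt_drop[!fear]) - 0.3)
})

test_that("the multi-subject corpus is reproducible and heterogeneous", {
  d1 <- synth_dataset(n_subjects = 3, seed = 43, n_trials = 2,
                      stimulus_s = 10, recovery_s = 2)
  d2 <- synth_dataset(n_subjects = 3, seed = 43, n_trials = 2,
                      stimulus_s = 10, recovery_s = 2)
  expect_identical(
    d1$sessions$V01$trials[[1]]$channels$ECG$values,
    d2$sessions$V01$trials[[1]]$channels$ECG$values)
  hrs <- vapply(d1$profiles, `[[`, numeric(1), "baseline_hr")
  expect_gt(max(hrs) - min(hrs), 1)   # drawn per subject
  expect_true(all(hrs >= 55 & hrs <= 85))
  expect_equal(nrow(d1$manifest), 6)
  expect_error(synth_dataset(n_subjects = 1), "n_subjects")
})
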