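# Synthetic multi-subject session generator with ground-truth physiology,
# emulating the structure of the reference recordings: trials of 30 s
# neutral recovery + 60 s stimulus + 30 s neutral recovery at 256 Hz, 20
# trials per subject, SAM self-reports coupled to the imposed
# fear/neutral condition.

bandlimited_noise <- function(n, fs, cutoff_hz, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  if (cutoff_hz < fs / 2)
    x <- apply_fir(x, fir_taps("lowpass", cutoff_hz, fs, 129))
  x * sd_target / stats::sd(x)
}

pqrst_template <- function(fs) {
  # Gaussian bumps at fixed offsets from the R wave (seconds, mV, widths)
  off <- c(p = -0.20, q = -0.045, r = 0.0, s = 0.045, t = 0.30)
  amp <- c(p = 0.12, q = -0.15, r = 1.0, s = -0.22, t = 0.35)
  wid <- c(p = 0.045, q = 0.012, r = 0.016, s = 0.014, t = 0.065)
  t <- seq(-0.45, 0.65, by = 1 / fs)
  y <- numeric(length(t))
  for (k in seq_along(off)) y <- y + amp[k] * exp(-(t - off[k])^2 /
                                                    (2 * wid[k]^2))
  list(t = t, y = y)
}

rr_sequence <- function(total_s, mean_rr_fn, sd_fn, phi = 0.9) {
  # AR(1) beat-to-beat intervals with time-varying stationary mean/SD,
  # truncated below at 0.3 s
  times <- numeric(0)
  t <- mean_rr_fn(0) / 2            # first beat half an interval in
  z <- 0   # standardized AR(1) state
  while (t < total_s) {
    times <- c(times, t)
    z <- phi * z + stats::rnorm(1, 0, sqrt(max(1 - phi^2, 0)))
    rr <- max(mean_rr_fn(t) + sd_fn(t) * z, 0.3)
    t <- t + rr
  }
  times
}

#' Synthesize an ECG channel with ground-truth beat times
#'
#' PQRST-shaped beats (a sum of Gaussian bumps) placed at inter-beat
#' intervals drawn from a positive-truncated AR(1) process with stationary
#' mean `60 / hr_mean` seconds and standard deviation `sdnn`, plus
#' band-limited (< 40 Hz) additive noise at `snr_db`. With `sdnn = 0` the
#' beat train is exactly periodic.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s length in seconds.
#' @param hr_mean mean heart rate in bpm (45–120), or a function of time
#'   returning bpm for condition-modulated trials.
#' @param sdnn beat-to-beat standard deviation in seconds, or a function
#'   of time.
#' @param seed integer seed.
#' @param snr_db signal-to-noise ratio of the additive noise (default 20).
#' @return List `values` (mV) and `r_times` (ground-truth R-peak times, s).
#' @export
synth_ecg <- function(fs, duration_s, hr_mean, sdnn, seed, snr_db = 20) {
  hr_fn <- if (is.function(hr_mean)) hr_mean else function(t) hr_mean
  sd_fn <- if (is.function(sdnn)) sdnn else function(t) sdnn
  probe <- vapply(seq(0, duration_s, length.out = 16), hr_fn, numeric(1))
  if (any(probe < 45) || any(probe > 120))
    stop("heart rate must stay within [45, 120] bpm")
  with_seed(seed, {
    r_times <- rr_sequence(duration_s, function(t) 60 / hr_fn(t), sd_fn)
    n <- round(duration_s * fs)
    y <- numeric(n)
    tpl <- pqrst_template(fs)
    for (rt in r_times) {
      i0 <- round((rt + tpl$t[1]) * fs) + 1L
      idx <- i0:(i0 + length(tpl$y) - 1L)
      ok <- idx >= 1L & idx <= n
      y[idx[ok]] <- y[idx[ok]] + tpl$y[ok]
    }
    sig_sd <- stats::sd(y)
    noise_sd <- sig_sd / 10^(snr_db / 20)
    list(values = y + bandlimited_noise(n, fs, 40, noise_sd),
         r_times = r_times)
  })
}

bateman_pulse <- function(t, amplitude, tau_r = 0.75, tau_d = 4) {
  # unit-peak double-exponential skin-conductance response kernel
  h <- exp(-t / tau_d) - exp(-t / tau_r)
  t_peak <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  h_peak <- exp(-t_peak / tau_d) - exp(-t_peak / tau_r)
  amplitude * h / h_peak
}

#' Synthesize a GSR channel with ground-truth SCR events
#'
#' Tonic level plus slow drift (linear and sinusoidal) plus Poisson-timed
#' skin-conductance responses shaped by a double-exponential kernel
#' `A (e^(-t/tau_d) - e^(-t/tau_r))` with rise constant 0.75 s and decay
#' constant drawn uniformly from 2–10 s, plus low-frequency measurement
#' noise at `snr_db` relative to the phasic component.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s length in seconds.
#' @param tonic baseline conductance in µS (>= 0).
#' @param drift linear drift in µS per minute.
#' @param scr_rate events per minute (>= 0), or a function of time.
#' @param amp_range SCR amplitude range in µS (uniform draw).
#' @param seed integer seed.
#' @param snr_db noise level relative to the phasic signal (default 20).
#' @return List `values` (µS) and `events` (`data.frame` with ground-truth
#'   `onset_s`, `amplitude`, `rise_time_s`).
#' @export
synth_gsr <- function(fs, duration_s, tonic, drift = 0, scr_rate = 2,
                      amp_range = c(0.1, 1), seed = 1, snr_db = 20) {
  if (tonic < 0) stop("tonic level must be non-negative")
  rate_fn <- if (is.function(scr_rate)) scr_rate else function(t) scr_rate
  if (rate_fn(0) < 0) stop("scr_rate must be non-negative")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    base <- tonic + drift * t / 60 +
      0.05 * tonic * sin(2 * pi * t / duration_s + stats::runif(1, 0, 2 * pi))
    # thinned Poisson process supports a time-varying rate
    rmax <- max(vapply(seq(0, duration_s, length.out = 32), rate_fn,
                       numeric(1)))
    events <- data.frame(onset_s = numeric(0), amplitude = numeric(0),
                         rise_time_s = numeric(0))
    phasic <- numeric(n)
    if (rmax > 0) {
      n_cand <- stats::rpois(1, rmax * duration_s / 60)
      onsets <- sort(stats::runif(n_cand, 0, duration_s - 5))
      keep <- stats::runif(n_cand) < vapply(onsets, rate_fn,
                                            numeric(1)) / rmax
      onsets <- onsets[keep]
      for (on in onsets) {
        A <- stats::runif(1, amp_range[1], amp_range[2])
        tau_d <- stats::runif(1, 2, 10)
        idx <- which(t >= on)
        phasic[idx] <- phasic[idx] +
          bateman_pulse(t[idx] - on, A, tau_d = tau_d)
        t_peak <- log(tau_d / 0.75) * 0.75 * tau_d / (tau_d - 0.75)
        events <- rbind(events, data.frame(onset_s = on, amplitude = A,
                                           rise_time_s = t_peak))
      }
    }
    noise_sd <- if (nrow(events)) stats::sd(phasic) / 10^(snr_db / 20)
    else 0.002
    list(values = base + phasic + bandlimited_noise(n, fs, 1.5, noise_sd),
         events = events)
  })
}

#' Synthesize a skin-temperature channel
#'
#' Baseline plus slow drift plus band-limited (< 0.2 Hz) noise realized as
#' a sum of random low-frequency sinusoids, so the spectrum is clean above
#' the band by construction.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s length in seconds.
#' @param base baseline temperature in °C (25–40).
#' @param drift_per_min linear drift in °C per minute, or a function of
#'   time returning the accumulated offset in °C.
#' @param seed integer seed.
#' @param noise_sd noise standard deviation in °C (default 0.02).
#' @return Numeric vector of samples (°C).
#' @export
synth_skt <- function(fs, duration_s, base, drift_per_min = 0, seed = 1,
                      noise_sd = 0.02) {
  if (base < 25 || base > 40)
    stop("baseline temperature must lie in [25, 40] degrees C")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    offset <- if (is.function(drift_per_min))
      vapply(t, drift_per_min, numeric(1))
    else drift_per_min * t / 60
    noise <- numeric(n)
    if (noise_sd > 0) {
      for (k in 1:20) {
        f <- stats::runif(1, 0.01, 0.15)
        noise <- noise + sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
      noise <- noise * noise_sd / stats::sd(noise)
    }
    base + offset + noise
  })
}

#' End-to-end SCR amplitude recovery errors
#'
#' Validation oracle for the electrodermal chain: generates long GSR
#' records with known events, runs the full detection pipeline (2 Hz
#' low-pass, decimation to 32 Hz, moving-median tonic/phasic split,
#' 0.8 Hz phasic smoothing, trough-to-peak detection) and returns the
#' relative amplitude error of every recovered isolated event. Events with
#' a neighbor closer than `isolation_s` are excluded: responses riding on
#' another response's decay have a genuinely smaller trough-to-peak
#' amplitude than their kernel amplitude. A missed event scores a full
#' error of 1. The tonic median span defaults to 80 s — sized for these
#' multi-minute validation records, not for 20 s analysis windows.
#'
#' @param seeds integer seeds, one record per seed.
#' @param duration_s record length (default 300 s).
#' @param scr_rate events per minute (default 1.5).
#' @param snr_db generator noise level (default 20).
#' @param isolation_s isolation radius in seconds (default 20).
#' @param median_s tonic median span in seconds (default 80).
#' @param amp_threshold detection threshold in µS (default 0.05).
#' @return Numeric vector of per-event relative amplitude errors.
#' @export
scr_recovery_errors <- function(seeds = 1:6, duration_s = 300,
                                scr_rate = 1.5, snr_db = 20,
                                isolation_s = 20, median_s = 80,
                                amp_threshold = 0.05) {
  errs <- numeric(0)
  for (s in seeds) {
    g <- synth_gsr(256, duration_s, tonic = 6, drift = 0.05,
                   scr_rate = scr_rate, amp_range = c(0.3, 0.8),
                   seed = 60 + s, snr_db = snr_db)
    truth <- g$events[order(g$events$onset_s), , drop = FALSE]
    iso <- vapply(seq_len(nrow(truth)), function(i) {
      others <- truth$onset_s[-i]
      all(abs(others - truth$onset_s[i]) > isolation_s) &&
        truth$onset_s[i] > isolation_s
    }, logical(1))
    truth <- truth[iso, , drop = FALSE]
    dec <- decimate_signal(filter_lowpass(g$values, 256, 2), 256, 32)
    phasic <- gsr_decompose(dec$values, dec$fs, median_s)$phasic
    phasic <- filter_lowpass(phasic, dec$fs, 0.8, 65)
    det <- detect_scrs(phasic, dec$fs, amp_threshold)
    for (i in seq_len(nrow(truth))) {
      hit <- which(abs(det$onset_index / dec$fs - truth$onset_s[i]) < 2)
      if (length(hit)) {
        hit <- hit[which.max(det$amplitude[hit])]
        errs <- c(errs, abs(det$amplitude[hit] - truth$amplitude[i]) /
                    truth$amplitude[i])
      } else errs <- c(errs, 1)
    }
  }
  errs
}

#' Subject profile for the synthetic generator
#'
#' @param baseline_hr resting heart rate in bpm (45–120).
#' @param sdnn_base beat-to-beat variability in seconds.
#' @param tonic_gsr tonic skin conductance in µS.
#' @param scr_rate_base non-specific SCR rate, events/min.
#' @param skt_base baseline skin temperature in °C.
#' @param report_noise_sd SAM rating noise, scale units.
#' @return List of class `"subject_profile"`.
#' @export
subject_profile <- function(baseline_hr = 70, sdnn_base = 0.05,
                            tonic_gsr = 6, scr_rate_base = 2,
                            skt_base = 33, report_noise_sd = 0.7) {
  stopifnot(baseline_hr >= 45, baseline_hr <= 120, tonic_gsr >= 0,
            scr_rate_base >= 0)
  structure(list(baseline_hr = baseline_hr, sdnn_base = sdnn_base,
                 tonic_gsr = tonic_gsr, scr_rate_base = scr_rate_base,
                 skt_base = skt_base, report_noise_sd = report_noise_sd),
            class = "subject_profile")
}

#' Fear condition effect
#'
#' Sympathetic-activation pattern applied to the stimulus span of fear
#' trials: heart rate up, beat-to-beat variability down, SCR rate and
#' amplitude up, skin temperature down; self-report targets sit in the
#' fear octant (low valence, high arousal, low dominance) for fear trials
#' and the opposite octant for neutral ones.
#'
#' @param hr_delta heart-rate increase in bpm.
#' @param sdnn_factor multiplicative change of beat-to-beat variability.
#' @param scr_rate_factor multiplicative change of the SCR rate.
#' @param scr_amp_factor multiplicative change of SCR amplitudes.
#' @param skt_delta skin-temperature change in °C.
#' @param pad_fear,pad_neutral target (valence, arousal, dominance) means.
#' @return List of class `"condition_effect"`.
#' @export
condition_effect <- function(hr_delta = 10, sdnn_factor = 0.6,
                             scr_rate_factor = 2, scr_amp_factor = 1.5,
                             skt_delta = -0.3,
                             pad_fear = c(2, 8, 2),
                             pad_neutral = c(7, 3, 7)) {
  stopifnot(sdnn_factor > 0, scr_rate_factor > 0, scr_amp_factor > 0)
  structure(list(hr_delta = hr_delta, sdnn_factor = sdnn_factor,
                 scr_rate_factor = scr_rate_factor,
                 scr_amp_factor = scr_amp_factor, skt_delta = skt_delta,
                 pad_fear = pad_fear, pad_neutral = pad_neutral),
            class = "condition_effect")
}

#' A zero condition effect (null hypothesis generator)
#'
#' Fear and neutral trials share identical physiology and identical
#' mid-scale self-report targets apart from the coupled label draw; use it
#' to verify that downstream classification stays at chance.
#'
#' @return A [condition_effect()] with no physiological or report contrast.
#' @export
null_effect <- function() {
  condition_effect(hr_delta = 0, sdnn_factor = 1, scr_rate_factor = 1,
                   scr_amp_factor = 1, skt_delta = 0,
                   pad_fear = c(2, 8, 2), pad_neutral = c(7, 3, 7))
}

smooth_step <- function(t, t0, t1, ramp = 5) {
  # 0 outside [t0, t1], 1 inside, smooth 'ramp'-second shoulders
  up <- stats::plogis((t - t0) / (ramp / 6))
  down <- stats::plogis((t1 - t) / (ramp / 6))
  up * down
}

#' Synthesize one subject session
#'
#' Each trial is 30 s neutral recovery + 60 s stimulus + 30 s neutral
#' recovery at `fs`. `round(fear_fraction * n_trials)` trials (positions
#' seeded) impose the [condition_effect()] on the stimulus span only:
#' heart rate and variability are modulated through the beat process, the
#' SCR rate/amplitude through the Poisson intensity, and skin temperature
#' through a smooth-shouldered step. The SAM self-report is drawn around
#' the per-condition targets with `report_noise_sd`, rounded and clipped
#' to 1–9.
#'
#' @param profile a [subject_profile()].
#' @param effect a [condition_effect()].
#' @param subject_id identifier for the session.
#' @param n_trials number of trials (default 20).
#' @param fear_fraction fraction of fear trials (default 0.2).
#' @param seed integer seed.
#' @param fs sampling rate (default 256 Hz).
#' @param stimulus_s,recovery_s span lengths (defaults 60 and 30 s).
#' @param snr_db ECG/GSR noise level (default 20).
#' @return List `session` (a [session()]) and `truth` (`data.frame` of
#'   trial conditions plus per-trial ground-truth beat times and SCR
#'   events as list columns).
#' @export
synth_session <- function(profile, effect = condition_effect(),
                          subject_id = "S1", n_trials = 20,
                          fear_fraction = 0.2, seed = 1, fs = 256,
                          stimulus_s = 60, recovery_s = 30, snr_db = 20) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(effect, "condition_effect"),
            fear_fraction >= 0, fear_fraction <= 1)
  duration_s <- stimulus_s + 2 * recovery_s
  n_fear <- round(fear_fraction * n_trials)
  fear_idx <- with_seed(seed, sample(n_trials, n_fear))
  trials <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  t0 <- recovery_s; t1 <- recovery_s + stimulus_s
  for (i in seq_len(n_trials)) {
    is_fear <- i %in% fear_idx
    tseed <- seed * 997L + i
    gate <- function(t) if (is_fear) smooth_step(t, t0, t1) else 0
    hr_fn <- function(t) profile$baseline_hr + effect$hr_delta * gate(t)
    sd_fn <- function(t) profile$sdnn_base *
      (1 + (effect$sdnn_factor - 1) * gate(t))
    rate_fn <- function(t) profile$scr_rate_base *
      (1 + (effect$scr_rate_factor - 1) * gate(t))
    amp_range <- c(0.1, 0.6) * if (is_fear) effect$scr_amp_factor else 1
    skt_fn <- function(t) effect$skt_delta * gate(t) * (is_fear) +
      -0.02 * t / 60   # mild habituation drift
    ecg <- synth_ecg(fs, duration_s, hr_fn, sd_fn, tseed, snr_db)
    gsr <- synth_gsr(fs, duration_s, profile$tonic_gsr, drift = 0.05,
                     scr_rate = rate_fn, amp_range = amp_range,
                     seed = tseed + 1L, snr_db = snr_db)
    skt <- synth_skt(fs, duration_s, profile$skt_base, skt_fn,
                     seed = tseed + 2L)
    targets <- if (is_fear) effect$pad_fear else effect$pad_neutral
    report <- with_seed(tseed + 3L, {
      r <- round(stats::rnorm(3, targets, profile$report_noise_sd))
      pmin(pmax(r, 1), 9)
    })
    tid <- sprintf("T%02d", i)
    trials[[i]] <- trial(tid, list(
      ECG = channel_signal("ECG", fs, ecg$values),
      GSR = channel_signal("GSR", fs, gsr$values),
      SKT = channel_signal("SKT", fs, skt)),
      self_report(report[1], report[2], report[3]),
      pre_recovery_s = recovery_s, post_recovery_s = recovery_s)
    truth[[i]] <- list(trial_id = tid, condition = if (is_fear) "fear"
                       else "neutral",
                       r_times = ecg$r_times, scr_events = gsr$events)
  }
  cond <- data.frame(
    subject_id = subject_id,
    trial_id = vapply(truth, `[[`, character(1), "trial_id"),
    condition = vapply(truth, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE)
  cond$r_times <- lapply(truth, `[[`, "r_times")
  cond$scr_events <- lapply(truth, `[[`, "scr_events")
  list(session = session(subject_id, trials), truth = cond)
}

#' Synthesize a multi-subject corpus
#'
#' Draws per-subject profiles from physiologically typical ranges
#' (heart rate 55–85 bpm, beat-to-beat SD 0.02–0.08 s, tonic conductance
#' 2–12 µS, SCR rate 1–4/min, skin temperature 31–35 °C) and generates one
#' session per subject; the manifest concatenates the per-trial ground
#' truth. Byte-reproducible for a given master seed.
#'
#' @param n_subjects number of subjects (>= 2, default 12).
#' @param effect a [condition_effect()] shared by all subjects.
#' @param seed master seed; subject seeds derive from it.
#' @param n_trials,fear_fraction,fs,stimulus_s,recovery_s,snr_db passed to
#'   [synth_session()].
#' @return List `sessions` (named list) and `manifest` (per-trial truth).
#' @export
synth_dataset <- function(n_subjects = 12, effect = condition_effect(),
                          seed = 1, n_trials = 20, fear_fraction = 0.2,
                          fs = 256, stimulus_s = 60, recovery_s = 30,
                          snr_db = 20) {
  stopifnot(n_subjects >= 2)
  profiles <- with_seed(seed, lapply(seq_len(n_subjects), function(i)
    subject_profile(baseline_hr = stats::runif(1, 55, 85),
                    sdnn_base = stats::runif(1, 0.02, 0.08),
                    tonic_gsr = stats::runif(1, 2, 12),
                    scr_rate_base = stats::runif(1, 1, 4),
                    skt_base = stats::runif(1, 31, 35))))
  sessions <- list()
  manifest <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("V%02d", i)
    out <- synth_session(profiles[[i]], effect, subject_id = sid,
                         n_trials = n_trials,
                         fear_fraction = fear_fraction,
                         seed = seed + 7919L * i, fs = fs,
                         stimulus_s = stimulus_s, recovery_s = recovery_s,
                         snr_db = snr_db)
    sessions[[sid]] <- out$session
    manifest[[i]] <- out$truth
  }
  list(sessions = sessions, manifest = do.call(rbind, manifest),
       profiles = profiles)
}
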