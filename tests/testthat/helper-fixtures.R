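# Shared fixtures, built in code. The heavier synthetic corpora used by
# the end-to-end checks are computed once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a minimal 2-trial synthetic session, reused by io/segmentation tests
small_session <- function() {
  fixture("small_session", function() {
    synth_session(subject_profile(), condition_effect(), subject_id = "S1",
                  n_trials = 2, fear_fraction = 0.5, seed = 11)
  })
}

make_trial <- function(duration_s, fs = 256, pre = 0, post = 0,
                       report = self_report(5, 5, 5), id = "T1") {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  trial(id, list(
    ECG = channel_signal("ECG", fs, sin(2 * pi * 1.2 * t)),
    GSR = channel_signal("GSR", fs, 5 + 0.1 * sin(2 * pi * 0.05 * t)),
    SKT = channel_signal("SKT", fs, 33 + 0.01 * t)),
    report, pre_recovery_s = pre, post_recovery_s = post)
}

# feature table for the strong-effect corpus: 2 subjects x 20 trials
strong_effect_table <- function() {
  fixture("strong_effect_table", function() {
    eff <- condition_effect(hr_delta = 15, scr_rate_factor = 3,
                            skt_delta = -0.5)
    ds <- synth_dataset(n_subjects = 2, effect = eff, seed = 202,
                        n_trials = 20, fear_fraction = 0.2)
    extract_feature_table(ds$sessions)
  })
}

# feature table for the null-effect corpus: 3 subjects x 20 trials
null_effect_table <- function() {
  fixture("null_effect_table", function() {
    ds <- synth_dataset(n_subjects = 3, effect = null_effect(), seed = 303,
                        n_trials = 20, fear_fraction = 0.3)
    extract_feature_table(ds$sessions)
  })
}
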