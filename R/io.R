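SENSORS <- c("ECG", "GSR", "SKT")

#' Construct a single-sensor signal
#'
#' @param sensor one of `"ECG"` (mV), `"GSR"` (µS), `"SKT"` (°C).
#' @param sampling_rate sampling rate in Hz (positive scalar).
#' @param values numeric vector of samples; must be non-empty and finite.
#' @return An object of class `"channel_signal"`.
#' @export
channel_signal <- function(sensor, sampling_rate, values) {
  sensor <- match.arg(toupper(sensor), SENSORS)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive finite scalar")
  values <- as.numeric(values)
  if (length(values) == 0) stop("channel '", sensor, "' has no samples")
  if (!all(is.finite(values)))
    stop("channel '", sensor, "' contains non-finite samples")
  structure(list(sensor = sensor, sampling_rate = sampling_rate,
                 values = values),
            class = "channel_signal")
}

#' Construct a SAM self-report
#'
#' Valence, arousal and dominance ratings on the 1–9 self-assessment
#' manikin scale.
#'
#' @param valence,arousal,dominance integers in 1..9.
#' @return An object of class `"self_report"`.
#' @export
self_report <- function(valence, arousal, dominance) {
  v <- c(valence = valence, arousal = arousal, dominance = dominance)
  if (!all(is.finite(v)) || any(v < 1) || any(v > 9))
    stop("self-report ratings must lie in [1, 9]; got (",
         paste(v, collapse = ", "), ")")
  structure(as.list(v), class = "self_report")
}

#' Construct a trial
#'
#' One stimulus presentation: three synchronized channels (ECG, GSR, SKT)
#' at a common sampling rate, the subject's self-report, and the length of
#' the neutral recovery slots padded before and after the stimulus.
#'
#' @param trial_id identifier, unique within a session.
#' @param channels named list with elements `ECG`, `GSR`, `SKT`, each a
#'   [channel_signal()] of equal length and rate.
#' @param report a [self_report()].
#' @param pre_recovery_s,post_recovery_s recovery padding in seconds
#'   (non-negative; their sum must be shorter than the recording).
#' @return An object of class `"trial"`.
#' @export
trial <- function(trial_id, channels, report,
                  pre_recovery_s = 0, post_recovery_s = 0) {
  if (!setequal(names(channels), SENSORS))
    stop("trial '", trial_id, "' must have exactly one channel per sensor (",
         paste(SENSORS, collapse = ", "), "); got: ",
         paste(names(channels), collapse = ", "))
  channels <- channels[SENSORS]
  ok <- vapply(channels, inherits, logical(1), "channel_signal")
  if (!all(ok)) stop("all channels must be channel_signal objects")
  fs <- unique(vapply(channels, `[[`, numeric(1), "sampling_rate"))
  lens <- vapply(channels, function(ch) length(ch$values), integer(1))
  if (length(fs) != 1)
    stop("trial '", trial_id, "': channels disagree on sampling rate")
  if (length(unique(lens)) != 1)
    stop("trial '", trial_id, "': channels have unequal lengths")
  if (!inherits(report, "self_report")) stop("report must be a self_report")
  if (pre_recovery_s < 0 || post_recovery_s < 0)
    stop("recovery paddings must be non-negative")
  dur <- lens[[1]] / fs
  if (dur < pre_recovery_s + post_recovery_s)
    stop("trial '", trial_id, "': duration (", dur,
         " s) shorter than combined recovery padding")
  structure(list(trial_id = as.character(trial_id), channels = channels,
                 report = report, pre_recovery_s = pre_recovery_s,
                 post_recovery_s = post_recovery_s),
            class = "trial")
}

trial_fs <- function(tr) tr$channels$ECG$sampling_rate
trial_length <- function(tr) length(tr$channels$ECG$values)
trial_duration <- function(tr) trial_length(tr) / trial_fs(tr)

#' Construct a session
#'
#' @param subject_id identifier.
#' @param trials non-empty list of [trial()] objects with unique ids.
#' @return An object of class `"session"`.
#' @export
session <- function(subject_id, trials) {
  if (!length(trials)) stop("session must contain at least one trial")
  ok <- vapply(trials, inherits, logical(1), "trial")
  if (!all(ok)) stop("all elements of `trials` must be trial objects")
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (anyDuplicated(ids))
    stop("duplicate trial ids within session '", subject_id, "'")
  names(trials) <- ids
  structure(list(subject_id = as.character(subject_id), trials = trials),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  fs <- trial_fs(x$trials[[1]])
  cat("session", x$subject_id, "-", length(x$trials), "trials at", fs, "Hz\n")
  invisible(x)
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("trial %s: %d samples/channel at %g Hz (%.1f s), report V=%d A=%d D=%d\n",
              x$trial_id, trial_length(x), trial_fs(x), trial_duration(x),
              x$report$valence, x$report$arousal, x$report$dominance))
  invisible(x)
}

#' Trim the neutral recovery slots from a trial
#'
#' Recordings are padded with neutral recovery segments before and after the
#' stimulus; these carry no stimulus-related physiology and are removed
#' before windowing. `round(pre_s * fs)` leading and `round(post_s * fs)`
#' trailing samples are dropped from every channel; the self-report is kept.
#'
#' @param tr a [trial()].
#' @param pre_s,post_s seconds to drop at the head and tail; default to the
#'   paddings recorded on the trial.
#' @return A trimmed [trial()] with zero recorded recovery padding.
#' @examples
#' # a 120 s recording with 30 s padding either side keeps the 60 s stimulus
#' @export
trim_recovery <- function(tr, pre_s = tr$pre_recovery_s,
                          post_s = tr$post_recovery_s) {
  stopifnot(inherits(tr, "trial"))
  if (pre_s < 0 || post_s < 0) stop("trim lengths must be non-negative")
  fs <- trial_fs(tr)
  n <- trial_length(tr)
  drop_head <- round(pre_s * fs)
  drop_tail <- round(post_s * fs)
  if (drop_head + drop_tail >= n)
    stop("trial '", tr$trial_id,
         "': trimming would leave an empty stimulus segment")
  keep <- (drop_head + 1):(n - drop_tail)
  channels <- lapply(tr$channels, function(ch) {
    channel_signal(ch$sensor, ch$sampling_rate, ch$values[keep])
  })
  trial(tr$trial_id, channels, tr$report, 0, 0)
}

#' Read sessions from the long-format CSV pair
#'
#' The native interchange format is a pair of plain CSV files: a samples
#' file with one row per sample (`subject_id, trial_id, sensor,
#' sample_index, value`; indices 0-based and contiguous per channel) and a
#' trials file with per-trial metadata (`subject_id, trial_id,
#' sampling_rate, valence, arousal, dominance, pre_recovery_s,
#' post_recovery_s`).
#'
#' @param samples_file,trials_file paths to the two CSV files.
#' @return Named list of [session()] objects, one per subject, in trials-file
#'   order.
#' @seealso [write_sessions()]
#' @export
read_sessions <- function(samples_file, trials_file) {
  samp <- utils::read.csv(samples_file, stringsAsFactors = FALSE)
  meta <- utils::read.csv(trials_file, stringsAsFactors = FALSE)
  need_s <- c("subject_id", "trial_id", "sensor", "sample_index", "value")
  need_m <- c("subject_id", "trial_id", "sampling_rate", "valence",
              "arousal", "dominance", "pre_recovery_s", "post_recovery_s")
  if (!all(need_s %in% names(samp)))
    stop("samples file lacks column(s): ",
         paste(setdiff(need_s, names(samp)), collapse = ", "))
  if (!all(need_m %in% names(meta)))
    stop("trials file lacks column(s): ",
         paste(setdiff(need_m, names(meta)), collapse = ", "))
  samp$subject_id <- as.character(samp$subject_id)
  samp$trial_id <- as.character(samp$trial_id)
  key <- paste(samp$subject_id, samp$trial_id, samp$sensor, sep = "\r")
  split_idx <- split(seq_len(nrow(samp)), key)
  sessions <- list()
  for (subj in unique(as.character(meta$subject_id))) {
    msub <- meta[meta$subject_id == subj, , drop = FALSE]
    trials <- vector("list", nrow(msub))
    for (i in seq_len(nrow(msub))) {
      tid <- as.character(msub$trial_id[i])
      chans <- list()
      for (sens in SENSORS) {
        idx <- split_idx[[paste(subj, tid, sens, sep = "\r")]]
        if (is.null(idx))
          stop("trial '", tid, "' of subject '", subj,
               "' lacks ", sens, " samples")
        block <- samp[idx, , drop = FALSE]
        block <- block[order(block$sample_index), , drop = FALSE]
        if (!identical(as.integer(block$sample_index),
                       seq_len(nrow(block)) - 1L))
          stop("trial '", tid, "' ", sens,
               ": sample_index not contiguous from 0")
        chans[[sens]] <- channel_signal(sens, msub$sampling_rate[i],
                                        block$value)
      }
      trials[[i]] <- trial(tid, chans,
                           self_report(msub$valence[i], msub$arousal[i],
                                       msub$dominance[i]),
                           msub$pre_recovery_s[i], msub$post_recovery_s[i])
    }
    sessions[[subj]] <- session(subj, trials)
  }
  sessions
}

#' Write sessions to the long-format CSV pair
#'
#' Inverse of [read_sessions()]; the round trip preserves sample values at
#' full precision.
#'
#' @param sessions a single [session()] or a list of them.
#' @param samples_file,trials_file output paths.
#' @return Invisibly, the list of sessions written.
#' @export
write_sessions <- function(sessions, samples_file, trials_file) {
  if (inherits(sessions, "session")) sessions <- list(sessions)
  samp_parts <- list()
  meta_parts <- list()
  for (ses in sessions) {
    stopifnot(inherits(ses, "session"))
    for (tr in ses$trials) {
      meta_parts[[length(meta_parts) + 1L]] <- data.frame(
        subject_id = ses$subject_id, trial_id = tr$trial_id,
        sampling_rate = trial_fs(tr),
        valence = tr$report$valence, arousal = tr$report$arousal,
        dominance = tr$report$dominance,
        pre_recovery_s = tr$pre_recovery_s,
        post_recovery_s = tr$post_recovery_s,
        stringsAsFactors = FALSE)
      for (sens in SENSORS) {
        v <- tr$channels[[sens]]$values
        samp_parts[[length(samp_parts) + 1L]] <- data.frame(
          subject_id = ses$subject_id, trial_id = tr$trial_id,
          sensor = sens, sample_index = seq_along(v) - 1L, value = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  samp <- do.call(rbind, samp_parts)
  # full-precision numeric serialization
  samp$value <- formatC(samp$value, digits = 17, format = "g")
  utils::write.csv(samp, samples_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, meta_parts), trials_file,
                   row.names = FALSE, quote = FALSE)
  invisible(sessions)
}

#' Write / read a feature table
#'
#' A feature table holds one row per analysis window: identifiers
#' (`subject_id`, `trial_id`, `window_index`), the ordered named feature
#' columns of [feature_names()], and the binary `fear_label`. The CSV round
#' trip is lossless at full double precision and the column order is fixed.
#'
#' @param table a feature-table `data.frame`.
#' @param file path to the CSV file.
#' @return `read_feature_table()` returns the validated `data.frame`.
#' @export
write_feature_table <- function(table, file) {
  validate_feature_table(table)
  out <- table
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 17,
                                                 format = "g")
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_feature_table(tab)
  tab$subject_id <- as.character(tab$subject_id)
  tab$trial_id <- as.character(tab$trial_id)
  tab
}

validate_feature_table <- function(tab) {
  id_cols <- c("subject_id", "trial_id", "window_index")
  profile <- if ("gsr.iqr" %in% names(tab)) "iqr" else "separate"
  want <- c(id_cols, feature_names(profile), "fear_label")
  if (!identical(names(tab), want)) {
    extra <- setdiff(names(tab), want)
    miss <- setdiff(want, names(tab))
    stop("feature table schema mismatch",
         if (length(extra)) paste0("; unknown column(s): ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing column(s): ",
                                  paste(miss, collapse = ", ")),
         if (!length(extra) && !length(miss)) "; columns out of order")
  }
  feat <- tab[feature_names(profile)]
  if (nrow(tab) && !all(vapply(feat, function(x) all(is.finite(x)),
                               logical(1))))
    stop("feature table contains non-finite feature values")
  if (nrow(tab) && !all(tab$fear_label %in% c(0L, 1L)))
    stop("fear_label must be binary 0/1")
  invisible(tab)
}
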