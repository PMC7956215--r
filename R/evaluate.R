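# Subject-dependent and subject-independent (leave-one-subject-out)
# evaluation protocols.

table_xy <- function(table) {
  feats <- feature_cols(table)
  list(x = as.matrix(table[feats]), y = as.integer(table$fear_label))
}

fold_metrics <- function(x, y, algorithm, hp, folds, seed) {
  # metrics per validation fold, averaged; falls back to pooling the
  # validation predictions when a fold lacks one class (AUC undefined)
  per_fold <- list()
  pooled_sc <- numeric(0); pooled_pred <- integer(0); pooled_y <- integer(0)
  thr <- 0.5 * (algorithm != "svm")
  for (f in seq_along(folds)) {
    p <- folds[[f]]
    fit <- fit_algo(x[p$train, , drop = FALSE], y[p$train], algorithm, hp,
                    seed + f)
    sc <- score_algo(fit, algorithm, x[p$test, , drop = FALSE])
    pred <- as.integer(sc > thr)
    pooled_sc <- c(pooled_sc, sc)
    pooled_pred <- c(pooled_pred, pred)
    pooled_y <- c(pooled_y, y[p$test])
    if (length(unique(y[p$test])) == 2)
      per_fold[[length(per_fold) + 1L]] <-
        compute_metrics(confusion_counts(y[p$test], pred), sc, y[p$test])
  }
  pooled_cm <- confusion_counts(pooled_y, pooled_pred)
  if (length(per_fold) == length(folds)) {
    agg <- aggregate_models(per_fold)
    ms <- structure(as.list(stats::setNames(agg$mean, agg$metric)),
                    class = "metric_set")
  } else {
    ms <- compute_metrics(pooled_cm, pooled_sc, pooled_y)
  }
  list(metrics = ms, cm = pooled_cm)
}

#' Subject-dependent evaluation
#'
#' One model per subject: hyperparameters are tuned by
#' [tune_and_train()] on the subject's own windows (stratified k-fold
#' objective), then the chosen configuration is scored by stratified
#' k-fold cross-validation on those windows, and the fold-averaged
#' validation metrics are reported. Subjects are aggregated with the mean
#' and the mean absolute deviation.
#'
#' @param table feature table (typically after [zscore_by_subject()]).
#' @param algorithm `"svm"`, `"knn"` or `"ensemble"`.
#' @param k folds (default 5).
#' @param budget hyperparameter-search evaluations per subject.
#' @param seed master seed; per-subject work is derived from it.
#' @return Object of class `"fear_eval"` with `per_model` (subject,
#'   confusion counts, metric set, hyperparameters) and `aggregate`
#'   (mean + MAD per metric).
#' @export
evaluate_subject_dependent <- function(table, algorithm = "svm", k = 5,
                                       budget = 30, seed = 1) {
  validate_feature_table(table)
  subs <- unique(table$subject_id)
  per_model <- list()
  for (i in seq_along(subs)) {
    sub_tab <- table[table$subject_id == subs[i], , drop = FALSE]
    xy <- table_xy(sub_tab)
    sseed <- seed + 101L * i
    model <- tune_and_train(xy$x, xy$y, algorithm, budget = budget, k = k,
                            seed = sseed)
    folds <- make_folds_xy(xy$y, k, sseed)
    fm <- fold_metrics(xy$x, xy$y, algorithm, model$hyperparameters, folds,
                       sseed)
    per_model[[i]] <- list(subject = subs[i], metrics = fm$metrics,
                           cm = fm$cm,
                           hyperparameters = model$hyperparameters)
  }
  structure(list(mode = "subject_dependent", algorithm = algorithm,
                 per_model = per_model,
                 aggregate = aggregate_models(
                   lapply(per_model, `[[`, "metrics")),
                 k = k, budget = budget, seed = seed),
            class = "fear_eval")
}

#' Leave-one-subject-out evaluation
#'
#' One model per subject: the held-out subject's windows never reach
#' hyperparameter search, scaling statistics or the final fit. With the
#' default `scale_mode = "subject"` the table is expected to be
#' per-subject standardized ([zscore_by_subject()]), which by construction
#' uses no cross-subject information; `scale_mode = "train"` instead
#' freezes mean/SD on the training pool and applies them to the held-out
#' subject.
#'
#' @param table feature table.
#' @param algorithm `"svm"`, `"knn"` or `"ensemble"`.
#' @param k folds of the tuning cross-validation.
#' @param budget hyperparameter-search evaluations per model.
#' @param seed master seed.
#' @param scale_mode `"subject"` (table already standardized per subject)
#'   or `"train"` (standardize here with training-pool statistics).
#' @return A `"fear_eval"` object; each `per_model` entry holds the
#'   held-out subject's confusion counts and metrics.
#' @export
evaluate_loso <- function(table, algorithm = "svm", k = 5, budget = 30,
                          seed = 1, scale_mode = c("subject", "train")) {
  scale_mode <- match.arg(scale_mode)
  validate_feature_table(table)
  plans <- make_splits(table, "loso")
  feats <- feature_cols(table)
  per_model <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    plan <- plans[[i]]
    tr_x <- as.matrix(table[plan$train, feats])
    te_x <- as.matrix(table[plan$test, feats])
    tr_y <- as.integer(table$fear_label[plan$train])
    te_y <- as.integer(table$fear_label[plan$test])
    if (scale_mode == "train") {
      mu <- colMeans(tr_x)
      sd_ <- apply(tr_x, 2, stats::sd)
      sd_[sd_ == 0 | !is.finite(sd_)] <- 1
      tr_x <- sweep(sweep(tr_x, 2, mu), 2, sd_, "/")
      te_x <- sweep(sweep(te_x, 2, mu), 2, sd_, "/")
    }
    sseed <- seed + 101L * i
    model <- tune_and_train(tr_x, tr_y, algorithm, budget = budget, k = k,
                            seed = sseed)
    sc <- predict(model, te_x, type = "score")
    pred <- predict(model, te_x, type = "class")
    cm <- confusion_counts(te_y, pred)
    ms <- if (length(unique(te_y)) == 2) compute_metrics(cm, sc, te_y)
    else structure(list(acc = (cm$tp + cm$tn) /
                          (cm$tp + cm$tn + cm$fp + cm$fn),
                        auc = NA_real_, gmean = NA_real_, f1 = NA_real_),
                   class = "metric_set")
    per_model[[i]] <- list(subject = plan$held_out_subject, metrics = ms,
                           cm = cm, hyperparameters = model$hyperparameters)
  }
  ok <- vapply(per_model, function(m) !is.na(m$metrics$auc), logical(1))
  structure(list(mode = "loso", algorithm = algorithm,
                 per_model = per_model,
                 aggregate = aggregate_models(
                   lapply(per_model[ok], `[[`, "metrics")),
                 k = k, budget = budget, seed = seed,
                 scale_mode = scale_mode),
            class = "fear_eval")
}

#' @export
print.fear_eval <- function(x, ...) {
  cat(sprintf("%s evaluation, %s classifier, %d model(s) [seed %d]\n",
              if (x$mode == "loso") "leave-one-subject-out"
              else "subject-dependent",
              x$algorithm, length(x$per_model), x$seed))
  for (m in x$per_model)
    cat(sprintf("  %-8s ACC %6.2f%%  AUC %6.2f%%  Gmean %6.2f%%  F1 %6.2f%%\n",
                m$subject, 100 * m$metrics$acc, 100 * m$metrics$auc,
                100 * m$metrics$gmean, 100 * m$metrics$f1))
  agg <- x$aggregate
  cat("  mean  ", paste(sprintf("%s %.2f%% (MAD %.2f%%)", agg$metric,
                                100 * agg$mean, 100 * agg$mad),
                        collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.fear_eval <- function(object, ...) object$aggregate
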