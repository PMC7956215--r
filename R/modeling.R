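# Classifier training with sequential model-based hyperparameter search,
# per-subject normalization and split construction.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

feature_cols <- function(table) {
  profile <- if ("gsr.iqr" %in% names(table)) "iqr" else "separate"
  feature_names(profile)
}

#' Per-subject z-score normalization
#'
#' Standardizes each feature within each subject using that subject's own
#' mean and standard deviation — the normalization that removes
#' between-subject physiological offsets before classification. Features
#' with zero variance within a subject are passed through as 0 with a
#' warning. (Because the statistics are per subject, normalizing a
#' held-out subject never touches the training subjects' values; an
#' alternative mode that freezes statistics on a training pool is
#' available through [evaluate_loso()]'s `scale_mode`.)
#'
#' @param table a feature table from [extract_feature_table()].
#' @return The table with feature columns standardized.
#' @export
zscore_by_subject <- function(table) {
  validate_feature_table(table)
  feats <- feature_cols(table)
  zero_var <- character(0)
  for (subj in unique(table$subject_id)) {
    idx <- which(table$subject_id == subj)
    if (length(idx) < 2)
      stop("subject '", subj, "' has a single sample; cannot standardize")
    for (f in feats) {
      v <- table[idx, f]
      s <- stats::sd(v)
      if (s == 0 || !is.finite(s)) {
        table[idx, f] <- 0
        zero_var <- c(zero_var, f)
      } else table[idx, f] <- (v - mean(v)) / s
    }
  }
  if (length(zero_var))
    warning("zero-variance feature(s) set to 0: ",
            paste(unique(zero_var), collapse = ", "))
  table
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    fold
  })
}

#' Build train/test split plans
#'
#' `scheme = "stratified_kfold"`: k folds preserving the class ratio within
#' one sample per fold. `scheme = "loso"`: one plan per subject, the
#' held-out subject entirely absent from the training pool (requires at
#' least 3 subjects).
#'
#' @param table a feature table.
#' @param scheme `"stratified_kfold"` or `"loso"`.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold shuffle.
#' @return For k-fold: list of `k` plans with `train`/`test` row indices;
#'   for LOSO: one plan per subject with `held_out_subject`, `train`,
#'   `test`. Every k-fold training part must contain both classes.
#' @export
make_splits <- function(table, scheme = c("stratified_kfold", "loso"),
                        k = 5, seed = 1) {
  scheme <- match.arg(scheme)
  validate_feature_table(table)
  if (scheme == "loso") {
    subs <- unique(table$subject_id)
    if (length(subs) < 3)
      stop("leave-one-subject-out needs at least 3 subjects")
    return(lapply(subs, function(s)
      list(held_out_subject = s,
           train = which(table$subject_id != s),
           test = which(table$subject_id == s))))
  }
  y <- table$fear_label
  fold <- stratified_folds(y, k, seed)
  plans <- lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
  for (p in plans)
    if (length(unique(y[p$train])) < 2)
      stop("a class is absent from a training fold; ",
           "too few samples of one class for k = ", k)
  plans
}

## ---- hyperparameter search spaces ------------------------------------

algo_space <- function(algorithm) {
  switch(algorithm,
    svm = list(
      decode = function(u) list(
        kernel = c("radial", "linear")[1 + (u[1] >= 0.5)],
        cost = 10^(-3 + 6 * u[2]),
        gamma = 10^(-3 + 4 * u[3])),
      d = 3),
    knn = list(
      decode = function(u) list(
        k = 1L + as.integer(floor(u[1] * 29.999)),
        metric = c("euclidean", "cityblock")[1 + (u[2] >= 0.5)],
        weighting = c("uniform", "distance")[1 + (u[3] >= 0.5)]),
      d = 3),
    ensemble = list(
      decode = function(u) list(
        trees = 10L + as.integer(floor(u[1] * 290.999)),
        depth = 1L + as.integer(floor(u[2] * 7.999)),
        learning_rate = 10^(-2 + 2 * u[3])),
      d = 3),
    stop("unknown algorithm: ", algorithm))
}

fit_algo <- function(x, y, algorithm, hp, seed) {
  switch(algorithm,
    svm = {
      yf <- factor(y, levels = c(0, 1))
      with_seed(seed, e1071::svm(
        x, yf, type = "C-classification", kernel = hp$kernel,
        cost = hp$cost,
        gamma = if (hp$kernel == "radial") hp$gamma else 1 / ncol(x),
        scale = FALSE))
    },
    knn = list(x = x, y = y, hp = hp),
    ensemble = with_seed(seed, xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$depth,
                    eta = hp$learning_rate, nthread = 1,
                    tree_method = "exact"),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$trees, verbose = 0)))
}

score_algo <- function(fit, algorithm, newx) {
  switch(algorithm,
    svm = {
      pr <- stats::predict(fit, newx, decision.values = TRUE)
      dv <- attr(pr, "decision.values")[, 1]
      # decision values are signed toward the first named class
      if (grepl("^0/", colnames(attr(pr, "decision.values"))[1])) -dv else dv
    },
    knn = {
      tr <- fit$x
      D <- matrix(0, nrow(newx), nrow(tr))
      if (fit$hp$metric == "euclidean") {
        for (j in seq_len(ncol(tr)))
          D <- D + outer(newx[, j], tr[, j], "-")^2
        D <- sqrt(D)
      } else {
        for (j in seq_len(ncol(tr)))
          D <- D + abs(outer(newx[, j], tr[, j], "-"))
      }
      k <- min(fit$hp$k, nrow(tr))
      vapply(seq_len(nrow(newx)), function(i) {
        ord <- order(D[i, ])[seq_len(k)]
        w <- if (fit$hp$weighting == "distance")
          1 / pmax(D[i, ord], 1e-10) else rep(1, k)
        sum(w * fit$y[ord]) / sum(w)
      }, numeric(1))
    },
    ensemble = stats::predict(fit, xgboost::xgb.DMatrix(newx,
                                                        nthread = 1)))
}

cv_misclassification <- function(x, y, algorithm, hp, folds, seed) {
  errs <- vapply(seq_along(folds), function(f) {
    p <- folds[[f]]
    fit <- fit_algo(x[p$train, , drop = FALSE], y[p$train], algorithm, hp,
                    seed + f)
    sc <- score_algo(fit, algorithm, x[p$test, , drop = FALSE])
    mean((sc > 0.5 * (algorithm != "svm")) != (y[p$test] == 1))
  }, numeric(1))
  mean(errs)
}

## ---- Gaussian-process surrogate with expected improvement -------------

gp_ei <- function(X, y, cand, lengthscale = 0.25) {
  sqdist <- function(a, b) {
    aa <- rowSums(a^2); bb <- rowSums(b^2)
    pmax(outer(aa, bb, "+") - 2 * tcrossprod(a, b), 0)
  }
  K <- exp(-sqdist(X, X) / (2 * lengthscale^2))
  diag(K) <- diag(K) + 1e-6 + 1e-4
  mu0 <- mean(y)
  alpha <- solve(K, y - mu0)
  Ks <- exp(-sqdist(cand, X) / (2 * lengthscale^2))
  mu <- mu0 + Ks %*% alpha
  v <- pmax(1 - rowSums(Ks * t(solve(K, t(Ks)))), 1e-12)
  s_y <- stats::sd(y)
  if (!is.finite(s_y) || s_y == 0) s_y <- 1e-8
  s <- pmax(sqrt(v) * s_y, 1e-8)
  ymin <- min(y)
  z <- (ymin - mu) / s
  as.numeric((ymin - mu) * stats::pnorm(z) + s * stats::dnorm(z))
}

#' Tune and train a fear classifier
#'
#' Sequential model-based optimization of the classifier's
#' hyperparameters: an initial Latin-hypercube design over the search
#' space is refined by a Gaussian-process surrogate with the
#' expected-improvement acquisition, each candidate scored by mean
#' stratified k-fold misclassification on the training data. The best
#' configuration is refitted on all training samples. Deterministic given
#' `seed`.
#'
#' Search spaces: SVM — kernel (radial/linear), cost `1e-3..1e3` (log),
#' kernel width `1e-3..1e1` (log); KNN — neighbors 1..30, metric
#' (euclidean/cityblock), weighting (uniform/distance); ensemble (boosted
#' decision trees) — trees 10..300, depth 1..8, learning rate `0.01..1`
#' (log).
#'
#' @param x numeric feature matrix (rows = windows).
#' @param y 0/1 labels; both classes must be present.
#' @param algorithm `"svm"`, `"knn"` or `"ensemble"`.
#' @param budget total number of objective evaluations (default 30).
#' @param k folds of the internal stratified cross-validation (default 5).
#' @param seed integer seed for the design, folds and stochastic fits.
#' @return Object of class `"fear_model"`: the fitted classifier, chosen
#'   `hyperparameters`, the cross-validated `cv_error`, search trace and
#'   seed.
#' @export
tune_and_train <- function(x, y, algorithm = c("svm", "knn", "ensemble"),
                           budget = 30, k = 5, seed = 1) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
  space <- algo_space(algorithm)
  folds <- make_folds_xy(y, k, seed)
  n0 <- min(max(4L, budget %/% 3L), budget)
  U <- with_seed(seed, lhs::randomLHS(n0, space$d))
  obj <- apply(U, 1, function(u)
    cv_misclassification(x, y, algorithm, space$decode(u), folds, seed))
  i <- n0
  while (i < budget) {
    cand <- with_seed(seed * 1000L + i, matrix(stats::runif(256 * space$d),
                                               ncol = space$d))
    ei <- gp_ei(U, obj, cand)
    u_next <- cand[which.max(ei), , drop = FALSE]
    U <- rbind(U, u_next)
    obj <- c(obj, cv_misclassification(x, y, algorithm,
                                       space$decode(u_next[1, ]), folds,
                                       seed))
    i <- i + 1L
  }
  best <- which.min(obj)
  hp <- space$decode(U[best, ])
  fit <- fit_algo(x, y, algorithm, hp, seed)
  structure(list(algorithm = algorithm, hyperparameters = hp, fit = fit,
                 cv_error = obj[best], n_evaluations = length(obj),
                 feature_names = colnames(x), seed = seed),
            class = "fear_model")
}

make_folds_xy <- function(y, k, seed) {
  fold <- stratified_folds(y, k, seed)
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Predict from a fitted fear classifier
#'
#' @param object a `"fear_model"` from [tune_and_train()].
#' @param newdata feature matrix with the training columns.
#' @param type `"class"` for 0/1 labels, `"score"` for decision values
#'   (higher = more fear-like; SVM scores are signed margins, KNN and
#'   ensemble scores are positive-class proportions/probabilities).
#' @param ... unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.fear_model <- function(object, newdata, type = c("class", "score"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  sc <- score_algo(object$fit, object$algorithm, newdata)
  if (type == "score") return(as.numeric(sc))
  thr <- 0.5 * (object$algorithm != "svm")
  as.integer(sc > thr)
}

#' @export
print.fear_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v) format(v, digits = 3),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("fear_model [%s]  %s\n", x$algorithm, hp))
  cat(sprintf("  cross-validated error %.4f over %d evaluations (seed %d)\n",
              x$cv_error, x$n_evaluations, x$seed))
  invisible(x)
}
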