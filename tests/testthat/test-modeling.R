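# A tiny hand-made feature table exercises the modeling layer without the
# cost of full signal extraction.
toy_table <- function(n_subj = 3, n_per = 40, signal = 2, seed = 19) {
  set.seed(seed)
  feats <- feature_names()
  rows <- lapply(seq_len(n_subj), function(s) {
    y <- rep(c(0, 1), length.out = n_per)
    x <- matrix(rnorm(n_per * length(feats)), n_per,
                dimnames = list(NULL, feats))
    # class signal in two features, plus a per-subject offset
    x[, "ecg.mean_ibi"] <- x[, "ecg.mean_ibi"] + signal * y + s * 3
    x[, "gsr.n_scr"] <- x[, "gsr.n_scr"] + signal * y - s
    cbind(data.frame(subject_id = sprintf("S%d", s),
                     trial_id = sprintf("T%02d", rep(1:(n_per / 2),
                                                     each = 2)),
                     window_index = rep(0:1, n_per / 2),
                     stringsAsFactors = FALSE),
          as.data.frame(x, check.names = FALSE),
          data.frame(fear_label = y))
  })
  do.call(rbind, rows)
}

test_that("per-subject z-scoring standardizes each block", {
  tab <- toy_table()
  z <- zscore_by_subject(tab)
  feats <- feature_names()
  for (s in unique(z$subject_id)) {
    block <- as.matrix(z[z$subject_id == s, feats])
    expect_lt(max(abs(colMeans(block))), 1e-10)
    expect_lt(max(abs(apply(block, 2, sd) - 1)), 1e-10)
  }
  # subjects differing only by an offset have identical transformed values
  tab2 <- toy_table(n_subj = 1)
  tab3 <- tab2
  tab3$subject_id <- "S9"
  tab3[feats] <- tab3[feats] + 100
  z23 <- zscore_by_subject(rbind(tab2, tab3))
  expect_equal(z23[z23$subject_id == "S9", feats],
               z23[z23$subject_id == "S1", feats],
               ignore_attr = TRUE, tolerance = 1e-9)
  # zero-variance feature passes through as zero, with a warning
  tab4 <- tab
  tab4$skt.sd <- 7
  expect_warning(z4 <- zscore_by_subject(tab4), "zero-variance")
  expect_true(all(z4$skt.sd == 0))
  # single-sample subject is an error
  tab5 <- rbind(tab, within(tab[1, ], subject_id <- "lonely"))
  expect_error(zscore_by_subject(tab5), "single sample")
})

test_that("stratified folds preserve the class ratio within one sample", {
  tab <- toy_table(n_subj = 1, n_per = 100, seed = 20)
  tab$fear_label <- c(rep(1, 30), rep(0, 70))
  plans <- make_splits(tab, "stratified_kfold", k = 5, seed = 2)
  expect_length(plans, 5)
  test_idx <- sort(unlist(lapply(plans, `[[`, "test")))
  expect_equal(test_idx, 1:100)          # folds partition the samples
  for (p in plans) {
    expect_equal(sum(tab$fear_label[p$test]), 6)
    expect_length(p$test, 20)
    expect_equal(sort(c(p$train, p$test)), 1:100)
  }
})

test_that("LOSO plans never leak the held-out subject", {
  tab <- toy_table()
  plans <- make_splits(tab, "loso")
  expect_length(plans, 3)
  for (p in plans) {
    expect_false(p$held_out_subject %in% tab$subject_id[p$train])
    expect_true(all(tab$subject_id[p$test] == p$held_out_subject))
    expect_equal(sort(c(p$train, p$test)), seq_len(nrow(tab)))
  }
  expect_error(make_splits(toy_table(n_subj = 2), "loso"), "at least 3")
})

test_that("separable blobs reach perfect validation accuracy", {
  set.seed(21)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 8), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(0, 1), each = n)
  for (algo in c("svm", "knn", "ensemble")) {
    m <- tune_and_train(x, y, algo, budget = 8, seed = 4)
    expect_equal(m$cv_error, 0, info = algo)
    expect_equal(predict(m, x), y, info = algo)
  }
})

test_that("tuning is deterministic under a fixed seed", {
  tab <- toy_table(n_subj = 1, n_per = 60, seed = 22)
  xy <- fearsense:::table_xy(tab)
  m1 <- tune_and_train(xy$x, xy$y, "svm", budget = 10, seed = 7)
  m2 <- tune_and_train(xy$x, xy$y, "svm", budget = 10, seed = 7)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$cv_error, m2$cv_error)
  m3 <- tune_and_train(xy$x, xy$y, "svm", budget = 10, seed = 8)
  expect_identical(predict(m1, xy$x), predict(m2, xy$x))
  expect_error(tune_and_train(xy$x, rep(1, length(xy$y)), "svm"),
               "both classes")
})

test_that("pure-noise features stay near chance AUC", {
  set.seed(23)
  x <- matrix(rnorm(120 * 5), 120)
  colnames(x) <- paste0("f", 1:5)
  y <- rep(c(0, 1), 60)
  m <- tune_and_train(x, y, "knn", budget = 6, seed = 5)
  set.seed(24)
  x_new <- matrix(rnorm(200 * 5), 200, dimnames = list(NULL, colnames(x)))
  y_new <- rep(c(0, 1), 100)
  a <- auc_score(predict(m, x_new, type = "score"), y_new)
  expect_gt(a, 0.35)
  expect_lt(a, 0.65)
})

test_that("the held-out subject cannot influence a LOSO model", {
  tab <- zscore_by_subject(toy_table(signal = 3))
  res1 <- evaluate_loso(tab, "knn", budget = 4, seed = 9)
  # poison the held-out subject's features: the model that tests S1 trains
  # only on S2+S3, so its training artifacts (chosen hyperparameters) must
  # be bit-identical — nothing of the held-out subject reaches tuning,
  # scaling or the fit
  poisoned <- tab
  idx <- poisoned$subject_id == "S1"
  poisoned[idx, feature_names()] <-
    poisoned[idx, feature_names()] + 1000
  res2 <- evaluate_loso(poisoned, "knn", budget = 4, seed = 9)
  expect_identical(res1$per_model[[1]]$hyperparameters,
                   res2$per_model[[1]]$hyperparameters)
  # and training a model directly on the S2+S3 pool ignores S1 entirely
  feats <- feature_names()
  pool1 <- tab[tab$subject_id != "S1", ]
  pool2 <- poisoned[poisoned$subject_id != "S1", ]
  m1 <- tune_and_train(as.matrix(pool1[feats]), pool1$fear_label, "knn",
                       budget = 4, seed = 12)
  m2 <- tune_and_train(as.matrix(pool2[feats]), pool2$fear_label, "knn",
                       budget = 4, seed = 12)
  clean_test <- as.matrix(tab[idx, feats])
  expect_identical(predict(m1, clean_test, type = "score"),
                   predict(m2, clean_test, type = "score"))
})

test_that("label permutation drives held-out performance to chance", {
  tab <- zscore_by_subject(toy_table(signal = 3, seed = 25))
  set.seed(26)
  tab$fear_label <- sample(tab$fear_label)
  res <- evaluate_loso(tab, "knn", budget = 4, seed = 10)
  aucs <- vapply(res$per_model, function(m) m$metrics$auc, numeric(1))
  expect_true(all(abs(aucs - 0.5) <= 0.15 + 1e-9))
})

test_that("subject-dependent evaluation recovers a strong toy signal", {
  tab <- zscore_by_subject(toy_table(signal = 5, seed = 27))
  res <- evaluate_subject_dependent(tab, "svm", budget = 6, seed = 11)
  expect_length(res$per_model, 3)
  expect_gt(res$aggregate$mean[res$aggregate$metric == "gmean"], 0.9)
  expect_s3_class(res, "fear_eval")
  agg <- summary(res)
  expect_equal(agg, res$aggregate)
})
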