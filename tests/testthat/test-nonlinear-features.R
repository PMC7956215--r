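test_that("delay estimation finds the first mutual-information minimum", {
  # a touch of noise keeps the histogram MI curve from plateauing, which
  # an exactly periodic noiseless series induces
  P <- 40
  set.seed(77)
  x <- sin(2 * pi * (1:800) / P) + rnorm(800, 0, 0.05)
  T <- estimate_delay(x, 30)
  expect_lte(abs(T - P / 4), 2)
  # agrees with the naive MI curve's first local minimum (same 5-point
  # smoothing applied to the independently computed curve)
  mi <- sapply(1:30, function(l) oracle_mi(x, l))
  sm <- as.numeric(stats::filter(mi, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- mi[is.na(sm)]
  first_min <- which(diff(sm) > 0)[1]
  expect_equal(T, first_min)

  set.seed(9)
  wn <- rnorm(2000)
  expect_lte(estimate_delay(wn, 20), 3)
  expect_error(estimate_delay(rep(1, 100), 10), "constant")
})

test_that("MI estimator matches the histogram oracle", {
  set.seed(10)
  x <- as.numeric(arima.sim(list(ar = 0.9), 500))
  for (lag in c(1, 5, 10))
    expect_equal(fearsense:::mutual_information_lag(x, lag),
                 oracle_mi(x, lag), tolerance = 1e-10)
})

test_that("false-nearest-neighbor dimension behaves on known systems", {
  # incommensurate period so exact duplicate points do not mask the fold
  x <- sin(2 * pi * (1:300) / 25.7)
  expect_equal(estimate_dimension(x, 6, max_dim = 6), 2)
  # chaotic logistic map embeds in low dimension
  y <- numeric(400); y[1] <- 0.31
  for (i in 2:400) y[i] <- 4 * y[i - 1] * (1 - y[i - 1])
  expect_lte(estimate_dimension(y, 1, max_dim = 6), 3)
  expect_error(estimate_dimension(rep(2, 50), 1), "constant")
  expect_error(estimate_dimension(sin(1:30), 10, max_dim = 5), "too short")
})

test_that("recurrence matrix equals the brute-force threshold computation", {
  set.seed(11)
  emb <- matrix(rnorm(100), ncol = 2)
  rp <- recurrence_matrix(emb)
  D <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50)
    D[i, j] <- sqrt(sum((emb[i, ] - emb[j, ])^2))
  expect_equal(rp$eps, 0.10 * mean(D[upper.tri(D)]))
  expect_identical(rp$R, (D <= rp$eps) * 1L)
  expect_true(all(rp$R == t(rp$R)))
  expect_true(all(diag(rp$R) == 1L))

  # rigid rotation leaves the matrix unchanged
  th <- 0.7
  rot <- emb %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_identical(recurrence_matrix(rot)$R, rp$R)

  # two distant clusters give a block-diagonal matrix
  emb2 <- rbind(matrix(rnorm(40, 0, 0.05), ncol = 2),
                matrix(rnorm(40, 50, 0.05), ncol = 2))
  R2 <- recurrence_matrix(emb2)$R
  expect_true(all(R2[1:20, 21:40] == 0))
  expect_true(all(R2[1:20, 1:20] == 1))

  expect_error(recurrence_matrix(matrix(1, 20, 2)), "degenerate")
  expect_error(recurrence_matrix(matrix(rnorm(10), ncol = 2)), "at least 10")
})

test_that("RQA measures agree exactly with line-enumeration oracles", {
  # all-ones matrix: RR = DET = LAM = 1 (exactly so with unit line minima;
  # with l_min = 2 only the two length-1 corner diagonals drop out)
  ones <- matrix(1L, 30, 30)
  m1 <- rqa_measures(ones, 1, 1, 1)
  expect_equal(m1$recurrence_rate, 1)
  expect_equal(m1$determinism, 1)
  expect_equal(m1$laminarity, 1)
  m1b <- rqa_measures(ones, 2, 2, 1)
  expect_gte(m1b$determinism, 0.99)
  expect_gte(m1b$laminarity, 0.99)

  # identity matrix with the main diagonal excluded: everything zero
  m0 <- rqa_measures(diag(1L, 30), 2, 2, 1)
  expect_equal(unlist(m0), c(recurrence_rate = 0, determinism = 0,
                             laminarity = 0, longest_diagonal = 0,
                             diagonal_entropy = 0, trapping_time = 0))

  # periodic signal: high determinism, exact agreement with the oracle
  x <- sin(2 * pi * (1:130) / 20)
  rp <- recurrence_matrix(embed_series(x, 5, 2))
  got <- rqa_measures(rp, 2, 2, 1)
  expect_gte(got$determinism, 0.9)
  expect_equal(got, oracle_rqa(rp$R, 2, 2, 1))

  # random sparse matrices, several parameter settings
  set.seed(12)
  for (rep in 1:3) {
    n <- c(40, 60, 90)[rep]
    R <- matrix(rbinom(n * n, 1, 0.15), n)
    R <- ((R + t(R)) > 0) * 1L
    diag(R) <- 1L
    for (params in list(c(2, 2, 1), c(3, 2, 2), c(2, 4, 0)))
      expect_equal(rqa_measures(R, params[1], params[2], params[3]),
                   oracle_rqa(R, params[1], params[2], params[3]))
  }
})

test_that("determinism and laminarity are monotone in the line minima", {
  set.seed(13)
  x <- as.numeric(arima.sim(list(ar = 0.95), 150))
  rp <- recurrence_matrix(embed_series(x, 2, 3))
  dets <- sapply(2:6, function(l) rqa_measures(rp, l, 2, 1)$determinism)
  lams <- sapply(2:6, function(v) rqa_measures(rp, 2, v, 1)$laminarity)
  expect_true(all(diff(dets) <= 1e-12))
  expect_true(all(diff(lams) <= 1e-12))
  expect_true(all(c(dets, lams) >= 0 & c(dets, lams) <= 1))
})

test_that("correlation dimension recovers known set dimensions", {
  set.seed(14)
  line <- cbind(runif(400), 0)
  expect_equal(correlation_dimension(line)$d2, 1.0, tolerance = 0.2)
  square <- matrix(runif(800), ncol = 2)
  expect_equal(correlation_dimension(square)$d2, 2.0, tolerance = 0.3 / 2)
  degenerate <- correlation_dimension(matrix(1, 120, 2))
  expect_equal(degenerate$d2, 0)
  expect_true(degenerate$flagged)
})

test_that("sample entropy equals the template-counting oracle", {
  set.seed(15)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  got <- sample_entropy(x, 2, r)
  expect_false(got$flagged)
  expect_equal(got$value, oracle_sampen(x, 2, r), tolerance = 1e-12)
  # cross-check against an independent implementation
  expect_equal(got$value, pracma::sample_entropy(x, edim = 2, r = r),
               tolerance = 1e-10)
  expect_true(sample_entropy(rep(1, 100), 2, 0)$flagged)
})

test_that("multiscale entropy of white noise decreases with scale", {
  ok <- 0
  for (seed in 1:6) {
    set.seed(100 + seed)
    mse <- multiscale_entropy(rnorm(800), 5, 2, 0.2)
    expect_false(mse$flagged)
    if (mse$values[5] < mse$values[1]) ok <- ok + 1
  }
  expect_gte(ok, 5)
  const <- multiscale_entropy(rep(2, 800))
  expect_equal(const$values, rep(0, 5))
  expect_true(const$flagged)
  expect_error(multiscale_entropy(rnorm(50), 5), "too short")
})

test_that("detrended fluctuation exponents match theory over seeds", {
  alphas_wn <- alphas_rw <- numeric(10)
  for (s in 1:10) {
    set.seed(200 + s)
    wn <- rnorm(2000)
    alphas_wn[s] <- dfa_alpha(wn)$alpha
    alphas_rw[s] <- dfa_alpha(cumsum(rnorm(2000)))$alpha
  }
  expect_equal(mean(alphas_wn), 0.5, tolerance = 0.1 / 0.5)
  expect_equal(mean(alphas_rw), 1.5, tolerance = 0.15 / 1.5)
  cst <- dfa_alpha(rep(1, 100))
  expect_equal(cst$alpha, 0)
  expect_true(cst$flagged)
  expect_error(dfa_alpha(rnorm(32)), "64")
})

test_that("feature extraction is deterministic for identical windows", {
  ses <- small_session()$session
  win <- segment_trial(trim_recovery(ses$trials[[1]]))[[2]]
  f1 <- extract_features(win)
  f2 <- extract_features(win)
  expect_identical(f1, f2)
  expect_named(f1, feature_names())
  expect_length(f1, 48)
})
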