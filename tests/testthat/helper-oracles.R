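# Brute-force oracles, kept deliberately naive and independent of the
# implementation they check.

oracle_mi <- function(x, lag, bins = 16) {
  a <- x[1:(length(x) - lag)]; b <- x[(lag + 1):length(x)]
  br <- seq(min(x), max(x), length.out = bins + 1)
  ia <- cut(a, br, include.lowest = TRUE, labels = FALSE)
  ib <- cut(b, br, include.lowest = TRUE, labels = FALSE)
  mi <- 0
  for (i in 1:bins) for (j in 1:bins) {
    pij <- mean(ia == i & ib == j)
    if (pij > 0) mi <- mi + pij * log(pij / (mean(ia == i) * mean(ib == j)))
  }
  mi
}

oracle_rqa <- function(R, l_min, v_min, theiler) {
  n <- nrow(R)
  Rx <- R
  for (i in 1:n) for (j in 1:n) if (abs(i - j) <= theiler) Rx[i, j] <- 0
  n_rec <- sum(Rx)
  rr <- n_rec / sum(abs(row(R) - col(R)) > theiler)
  dl <- integer(0)
  for (d in -(n - 1):(n - 1)) {
    if (abs(d) <= theiler) next
    run <- 0
    for (i in 1:n) {
      j <- i + d
      v <- if (j >= 1 && j <= n) R[i, j] else 0
      if (v == 1) run <- run + 1
      else { if (run > 0) dl <- c(dl, run); run <- 0 }
    }
    if (run > 0) dl <- c(dl, run)
  }
  vl <- integer(0)
  for (j in 1:n) {
    run <- 0
    for (i in 1:n) {
      if (Rx[i, j] == 1) run <- run + 1
      else { if (run > 0) vl <- c(vl, run); run <- 0 }
    }
    if (run > 0) vl <- c(vl, run)
  }
  dk <- dl[dl >= l_min]; vk <- vl[vl >= v_min]
  ent <- if (length(dk)) { p <- table(dk) / length(dk); -sum(p * log(p)) }
         else 0
  list(recurrence_rate = rr,
       determinism = if (n_rec) min(sum(dk) / n_rec, 1) else 0,
       laminarity = if (n_rec) min(sum(vk) / n_rec, 1) else 0,
       longest_diagonal = if (length(dl)) max(dl) else 0,
       diagonal_entropy = ent,
       trapping_time = if (length(vk)) mean(vk) else 0)
}

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    tot <- 0
    for (i in 1:(n - m)) for (j in 1:(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
        tot <- tot + 1
    }
    tot
  }
  -log(count(m + 1) / count(m))
}

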