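# Non-linear dynamics descriptors: phase-space embedding (delay by auto
# mutual information, dimension by false nearest neighbors), recurrence
# matrix and its quantification, Grassberger-Procaccia correlation
# dimension, multiscale sample entropy and detrended fluctuation analysis.

#' Delay embedding of a scalar series
#'
#' @param x numeric series.
#' @param T delay in samples (>= 1).
#' @param M embedding dimension (>= 1).
#' @return Matrix with `length(x) - (M - 1) * T` rows and `M` columns;
#'   row i is `(x[i], x[i + T], ..., x[i + (M-1) T])`.
#' @export
embed_series <- function(x, T, M) {
  stopifnot(T >= 1, M >= 1)
  n_pts <- length(x) - (M - 1) * T
  if (n_pts <= 0)
    stop("series too short for delay ", T, " and dimension ", M)
  sapply(seq_len(M), function(j) x[(1:n_pts) + (j - 1) * T])
}

mutual_information_lag <- function(x, lag, bins = 16) {
  a <- x[1:(length(x) - lag)]
  b <- x[(lag + 1):length(x)]
  br <- seq(min(x), max(x), length.out = bins + 1)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(a)
  pa <- tabulate(ia, nbins = bins) / length(a)
  pb <- tabulate(ib, nbins = bins) / length(a)
  nz <- joint > 0
  pp <- outer(pa, pb)
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Embedding delay from auto mutual information
#'
#' Computes the auto mutual information (16 equal-width bins) at lags
#' `1..max_lag` and returns the first local minimum of the lightly
#' smoothed curve (5-point moving average; histogram-noise ripples
#' otherwise trigger spurious early minima) — the canonical delay choice
#' for phase-space reconstruction. If the curve has no local minimum
#' within range, `max_lag` is returned with a warning.
#'
#' @param x numeric series (non-constant, length >= 4 * max_lag).
#' @param max_lag largest lag considered, in samples.
#' @param bins histogram bins for the MI estimate.
#' @param smooth half-width of the moving-average smoother (0 disables).
#' @return Integer delay in samples.
#' @export
estimate_delay <- function(x, max_lag, bins = 16, smooth = 2) {
  if (stats::sd(x) == 0) stop("constant series: delay undefined")
  if (length(x) < 4 * max_lag)
    stop("series must be at least 4 * max_lag samples long")
  mi <- vapply(seq_len(max_lag), function(l)
    mutual_information_lag(x, l, bins), numeric(1))
  if (smooth > 0 && max_lag > 2 * smooth + 1) {
    sm <- stats::filter(mi, rep(1 / (2 * smooth + 1), 2 * smooth + 1),
                        sides = 2)
    mi[!is.na(sm)] <- sm[!is.na(sm)]
  }
  for (l in seq_len(max_lag - 1)) {
    before_ok <- l == 1 || mi[l] < mi[l - 1]
    if (before_ok && mi[l] <= mi[l + 1]) return(as.integer(l))
  }
  warning("no local minimum of mutual information within max_lag; using max_lag")
  as.integer(max_lag)
}

#' Embedding dimension by false nearest neighbors
#'
#' For each candidate dimension `m`, finds every point's nearest neighbor
#' in the `m`-dimensional embedding and checks how much their separation
#' grows when the `(m+1)`-th coordinate is added. A neighbor is false when
#' the growth exceeds `Rtol` times the m-dimensional distance or the new
#' distance exceeds `Atol` times the attractor size (the series' standard
#' deviation). The smallest `m` with a false-neighbor fraction below
#' `threshold` is returned; if none qualifies, `max_dim` with a warning.
#'
#' @param x numeric series.
#' @param T embedding delay in samples.
#' @param max_dim largest dimension tried.
#' @param Rtol,Atol,threshold false-neighbor criteria (defaults 15, 2, 0.01).
#' @return Integer embedding dimension.
#' @export
estimate_dimension <- function(x, T, max_dim = 6, Rtol = 15, Atol = 2,
                               threshold = 0.01) {
  sigma <- stats::sd(x)
  if (sigma == 0) stop("constant series: dimension undefined")
  for (m in seq_len(max_dim)) {
    n_pts <- length(x) - m * T        # need the (m+1)-th coordinate too
    if (n_pts < 10)
      stop("series too short to test dimension ", m, " with delay ", T)
    emb <- embed_series(x[1:(n_pts + (m - 1) * T)], T, m)
    D <- as.matrix(stats::dist(emb))
    diag(D) <- Inf
    nn <- apply(D, 1, which.min)
    rm_d <- D[cbind(seq_len(n_pts), nn)]
    extra <- abs(x[(1:n_pts) + m * T] - x[nn + m * T])
    rm1 <- sqrt(rm_d^2 + extra^2)
    # floor the neighbor distance so numerically identical points (exact
    # recurrences of a periodic orbit) do not inflate the ratio test
    false1 <- extra > Rtol * pmax(rm_d, 1e-8 * sigma)
    false2 <- rm1 / sigma > Atol
    if (mean(false1 | false2) < threshold) return(as.integer(m))
  }
  warning("false-neighbor fraction never fell below threshold; using max_dim")
  as.integer(max_dim)
}

#' Recurrence matrix of an embedded series
#'
#' Thresholded pairwise-distance matrix: entry (i, j) is 1 when the
#' Euclidean distance between embedded points i and j is at most `E`,
#' where `E` is `e_frac` (default 10%) of the phase-space diameter — the
#' mean pairwise distance by default (`e_mode = "max"` uses the maximum).
#'
#' @param emb embedding matrix from [embed_series()] (>= 10 rows).
#' @param e_frac threshold fraction of the diameter.
#' @param e_mode `"mean"` or `"max"` diameter convention.
#' @return List of class `"recurrence_matrix"` with the binary matrix `R`
#'   (integer 0/1, symmetric, unit diagonal) and the threshold `eps`.
#' @export
recurrence_matrix <- function(emb, e_frac = 0.10,
                              e_mode = c("mean", "max")) {
  e_mode <- match.arg(e_mode)
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = 1)
  if (nrow(emb) < 10) stop("need at least 10 embedded points")
  D <- as.matrix(stats::dist(emb))
  diam <- if (e_mode == "mean") mean(D[upper.tri(D)]) else max(D)
  if (diam == 0) stop("degenerate embedding: all points identical")
  eps <- e_frac * diam
  R <- (D <= eps) * 1L
  dimnames(R) <- NULL
  structure(list(R = R, eps = eps), class = "recurrence_matrix")
}

line_lengths <- function(v) {
  r <- rle(v)
  r$lengths[r$values == 1L]
}

#' Recurrence quantification measures
#'
#' Line-structure statistics of a recurrence matrix, with a Theiler band of
#' `theiler` diagonals around the line of identity excluded everywhere:
#' \describe{
#'   \item{recurrence_rate}{density of recurrent points outside the band.}
#'   \item{determinism}{fraction of recurrent points lying on diagonal
#'     lines of length >= `l_min`.}
#'   \item{laminarity}{same for vertical lines of length >= `v_min`.}
#'   \item{longest_diagonal}{longest diagonal line off the identity band.}
#'   \item{diagonal_entropy}{Shannon entropy (nats) of the diagonal
#'     line-length distribution (lines >= `l_min`).}
#'   \item{trapping_time}{mean vertical line length (lines >= `v_min`).}
#' }
#' All measures are 0 when the corresponding structures are absent.
#'
#' @param rp a `"recurrence_matrix"` or a square binary matrix.
#' @param l_min,v_min minimum diagonal / vertical line lengths (default 2).
#' @param theiler number of sub/super-diagonals excluded around the
#'   identity (default 1, i.e. only the main diagonal).
#' @return Named list of the six measures.
#' @export
rqa_measures <- function(rp, l_min = 2, v_min = 2, theiler = 1) {
  R <- if (inherits(rp, "recurrence_matrix")) rp$R else rp
  n <- nrow(R)
  stopifnot(ncol(R) == n)
  off <- abs(row(R) - col(R))
  Rx <- R
  Rx[off <= theiler] <- 0L
  n_cells <- sum(off > theiler)
  n_rec <- sum(Rx)
  rr <- if (n_cells > 0) n_rec / n_cells else 0
  # diagonal lines over all diagonals outside the Theiler band (both
  # triangles scanned explicitly; no symmetry assumption)
  diag_lines <- integer(0)
  if (theiler + 1 <= n - 1) for (d in seq.int(theiler + 1, n - 1)) {
    i <- 1:(n - d)
    diag_lines <- c(diag_lines,
                    line_lengths(R[cbind(i, i + d)]),
                    line_lengths(R[cbind(i + d, i)]))
  }
  dl <- diag_lines[diag_lines >= l_min]
  det <- if (n_rec > 0) sum(dl) / n_rec else 0
  lmax <- if (length(diag_lines)) max(diag_lines) else 0
  if (length(dl)) {
    p <- table(dl) / length(dl)
    entr <- -sum(p * log(p))
  } else entr <- 0
  # vertical lines on the band-excluded matrix
  vert_lines <- unlist(lapply(seq_len(n), function(j) line_lengths(Rx[, j])))
  vl <- vert_lines[vert_lines >= v_min]
  lam <- if (n_rec > 0) sum(vl) / n_rec else 0
  tt <- if (length(vl)) mean(vl) else 0
  list(recurrence_rate = rr, determinism = min(det, 1),
       laminarity = min(lam, 1), longest_diagonal = as.numeric(lmax),
       diagonal_entropy = entr, trapping_time = tt)
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Slope of `log C(r)` against `log r`, where `C(r)` is the fraction of
#' point pairs closer than `r`, fitted over the scaling region between the
#' 2nd and 20th percentiles of the pairwise distances (staying below the
#' range where boundary saturation flattens the curve). Degenerate
#' geometries (identical points, collapsed percentile range) yield a
#' flagged 0.
#'
#' @param emb embedding matrix (>= 100 points for a stable estimate).
#' @param n_r number of log-spaced radii in the scaling region.
#' @return List `d2` (the slope) and `flagged`.
#' @export
correlation_dimension <- function(emb, n_r = 12) {
  if (is.null(dim(emb))) emb <- matrix(emb, ncol = 1)
  d <- as.numeric(stats::dist(emb))
  if (!length(d) || all(d == 0)) return(list(d2 = 0, flagged = TRUE))
  qs <- stats::quantile(d[d > 0], c(0.02, 0.20), names = FALSE)
  if (!all(is.finite(qs)) || qs[1] <= 0 || qs[2] <= qs[1])
    return(list(d2 = 0, flagged = TRUE))
  r <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_r))
  cr <- vapply(r, function(ri) mean(d < ri), numeric(1))
  ok <- cr > 0
  if (sum(ok) < 3) return(list(d2 = 0, flagged = TRUE))
  fit <- stats::lm.fit(cbind(1, log(r[ok])), log(cr[ok]))
  list(d2 = unname(fit$coefficients[2]), flagged = FALSE)
}

chebyshev_neighbors <- function(emb, r) {
  # count ordered pairs i != j with max-norm distance <= r
  n <- nrow(emb)
  total <- 0
  D <- abs(outer(emb[, 1], emb[, 1], "-"))
  if (ncol(emb) > 1)
    for (j in 2:ncol(emb))
      D <- pmax(D, abs(outer(emb[, j], emb[, j], "-")))
  sum(D <= r) - n
}

#' Sample entropy
#'
#' `-log(A / B)` where `B` counts template pairs of length `m` within
#' Chebyshev tolerance `r` and `A` the pairs still matching at length
#' `m + 1` (self-matches excluded). Returns flagged 0 when no template
#' pair matches at either length (including constant input with r = 0).
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance in signal units.
#' @return List `value`, `flagged`.
#' @export
sample_entropy <- function(x, m = 2, r) {
  n <- length(x)
  if (n < m + 2) stop("series too short for template length ", m)
  if (r <= 0) return(list(value = 0, flagged = TRUE))
  # templates of length m and m+1 over a common index range is the standard
  # convention: use n - m templates for both
  emb_m <- embed_series(x[1:(n)], 1, m)[1:(n - m), , drop = FALSE]
  emb_m1 <- embed_series(x, 1, m + 1)
  B <- chebyshev_neighbors(emb_m, r)
  A <- chebyshev_neighbors(emb_m1, r)
  if (B == 0 || A == 0) return(list(value = 0, flagged = TRUE))
  list(value = -log(A / B), flagged = FALSE)
}

#' Multiscale sample entropy
#'
#' Coarse-grains the series at scales `1..n_scales` (non-overlapping means
#' of `s` consecutive samples) and computes the sample entropy of each
#' coarse series with template length `m` and tolerance
#' `r_frac * sd(x)` — the tolerance is fixed from the original series so
#' the values are comparable across scales. Constant input yields flagged
#' zeros at every scale.
#'
#' @param x numeric series (length >= `10 * n_scales * (m + 1)`).
#' @param n_scales number of scales (default 5).
#' @param m template length (default 2).
#' @param r_frac tolerance as a fraction of the series' standard deviation.
#' @return List `values` (length `n_scales`) and `flagged`.
#' @export
multiscale_entropy <- function(x, n_scales = 5, m = 2, r_frac = 0.2) {
  if (length(x) < 10 * n_scales * (m + 1))
    stop("series too short for ", n_scales, " scales")
  r <- r_frac * stats::sd(x)
  vals <- numeric(n_scales)
  flagged <- FALSE
  for (s in seq_len(n_scales)) {
    nb <- floor(length(x) / s)
    coarse <- colMeans(matrix(x[1:(nb * s)], nrow = s))
    se <- sample_entropy(coarse, m, r)
    vals[s] <- se$value
    flagged <- flagged || se$flagged
  }
  list(values = vals, flagged = flagged)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-removed series, splits the profile into
#' non-overlapping boxes of log-spaced sizes from `min_box` to
#' `max_box_frac * N`, removes a linear trend per box, and returns the
#' slope alpha of `log F(n)` versus `log n`, where `F(n)` is the
#' root-mean-square residual fluctuation. Alpha is 0.5 for white noise and
#' 1.5 for its running sum. Constant input yields a flagged 0.
#'
#' @param x numeric series (length >= 64).
#' @param min_box smallest box size (default 4).
#' @param max_box_frac largest box as a fraction of the length (default 1/4).
#' @param n_boxes number of log-spaced box sizes tried.
#' @return List `alpha`, `flagged`.
#' @export
dfa_alpha <- function(x, min_box = 4, max_box_frac = 0.25, n_boxes = 10) {
  n <- length(x)
  if (n < 64) stop("detrended fluctuation analysis needs at least 64 samples")
  if (stats::sd(x) == 0) return(list(alpha = 0, flagged = TRUE))
  prof <- cumsum(x - mean(x))
  max_box <- floor(max_box_frac * n)
  sizes <- unique(round(exp(seq(log(min_box), log(max_box),
                                length.out = n_boxes))))
  fl <- vapply(sizes, function(s) {
    nb <- n %/% s
    m <- matrix(prof[1:(nb * s)], nrow = s)
    t <- seq_len(s)
    tc <- t - mean(t)
    denom <- sum(tc^2)
    slopes <- colSums(m * tc) / denom
    fitted <- outer(tc, slopes) +
      matrix(colMeans(m), nrow = s, ncol = nb, byrow = TRUE)
    sqrt(mean((m - fitted)^2))
  }, numeric(1))
  ok <- fl > 0
  if (sum(ok) < 3) return(list(alpha = 0, flagged = TRUE))
  fit <- stats::lm.fit(cbind(1, log(sizes[ok])), log(fl[ok]))
  list(alpha = unname(fit$coefficients[2]), flagged = FALSE)
}
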