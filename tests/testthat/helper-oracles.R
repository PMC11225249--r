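# Independent oracles used across the test files. These deliberately avoid
# the package's own arithmetic: brute force over dense grids, elementary
# loops, and closed forms.

# Brute-force TFN binary operation over the alpha = 0 supports: evaluates
# `f` on a dense grid (endpoints included) of the two support intervals and
# returns the (support_min, vertex, support_max) triple. For +, - and * the
# extrema over a box are attained at corners, which the grid contains, so
# the endpoints are exact.
grid_op_oracle <- function(a, b, f, n_grid = 41L) {
  ga <- seq(a[1], a[3], length.out = n_grid)
  gb <- seq(b[1], b[3], length.out = n_grid)
  vals <- outer(ga, gb, f)
  c(min(vals), f(a[2], b[2]), max(vals))
}

# Random valid TFN triple inside [lo, hi].
random_triple <- function(lo = -3, hi = 3) sort(stats::runif(3, lo, hi))

# Mean value of a TFN by numeric integration of alpha-cut midpoints:
# E(A) = int_0^1 (A^L(alpha) + A^U(alpha)) / 2 d alpha.
integral_mean_oracle <- function(a, n = 20001L) {
  alpha <- seq(0, 1, length.out = n)
  lower <- a[1] + alpha * (a[2] - a[1])
  upper <- a[3] - alpha * (a[3] - a[2])
  mean((lower + upper) / 2)
}

# Friedman statistics by elementary loops: rank each row (average ranks on
# ties) with explicit counting, then apply the definition of Q and F_f.
friedman_oracle <- function(scores) {
  N <- nrow(scores); k <- ncol(scores)
  ranks <- matrix(NA_real_, N, k)
  for (i in seq_len(N)) {
    for (j in seq_len(k)) {
      better <- sum(scores[i, ] > scores[i, j])
      tied <- sum(scores[i, ] == scores[i, j])
      ranks[i, j] <- better + (tied + 1) / 2
    }
  }
  rbar <- colSums(ranks) / N
  Q <- 12 * N / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  list(avg_ranks = rbar, Q = Q, F_f = (N - 1) * Q / (N * (k - 1) - Q))
}

# A classifier contract that always predicts the training majority class.
majority_classifier <- function() {
  list(fit = function(X, y) as.integer(mean(y) >= 0.5),
       predict = function(fit, X) rep(fit, nrow(X)))
}
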