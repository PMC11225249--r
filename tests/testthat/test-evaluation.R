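test_that("confusion counts the four cells and ignores row order", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(cm[c("TP", "TN", "FP", "FN")]),
               c(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  cm2 <- confusion(c(1, 1, 0), c(0, 0, 0))
  expect_equal(cm2$FN, 2L)
  expect_equal(cm2$TN, 1L)
  set.seed(2)
  y <- rbinom(60, 1, 0.4); p <- rbinom(60, 1, 0.5)
  perm <- sample(60)
  expect_identical(confusion(y, p), confusion(y[perm], p[perm]))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "same length")
  expect_error(confusion(c(1, 2), c(1, 0)), "0 or 1")
})

test_that("metrics implement the published formulas and edge conventions", {
  perfect <- classification_metrics(confusion_counts(10, 20, 0, 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "f1", "mcc")]),
               c(sensitivity = 1, specificity = 1, f1 = 1, mcc = 1))
  inverted <- suppressWarnings(
    classification_metrics(confusion_counts(0, 0, 10, 20)))
  expect_equal(inverted$mcc, -1)
  # zero-denominator cells return 0 with a warning
  warns <- capture_warnings(
    m0 <- classification_metrics(confusion_counts(0, 30, 0, 10)))
  expect_true(any(grepl("precision", warns)))
  expect_equal(m0$precision, 0)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$mcc, 0)
  # recall duplicates sensitivity; F1 is the harmonic mean
  m <- classification_metrics(confusion_counts(4, 82, 2, 11))
  expect_equal(m$recall, m$sensitivity)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  # F1 is invariant to TN
  m_tn <- classification_metrics(confusion_counts(4, 9999, 2, 11))
  expect_equal(m_tn$f1, m$f1)
  expect_error(classification_metrics(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("SMOTE balances classes with convex minority combinations", {
  set.seed(21)
  X <- rbind(matrix(rnorm(80, 0), ncol = 2),
             matrix(rnorm(12, 5), ncol = 2))
  y <- rep(c(0L, 1L), c(40, 6))
  out <- smote_balance(X, y)
  expect_equal(sum(out$y == 0), sum(out$y == 1))
  expect_equal(out$n_synthetic, 34L)
  expect_equal(out$X[seq_len(46), ], X)          # originals untouched
  # synthetic rows stay inside the minority bounding box (convexity)
  syn <- out$X[-(seq_len(46)), , drop = FALSE]
  minb <- apply(X[y == 1, ], 2, range)
  expect_true(all(syn[, 1] >= minb[1, 1] - 1e-12 & syn[, 1] <= minb[2, 1] + 1e-12))
  expect_true(all(syn[, 2] >= minb[1, 2] - 1e-12 & syn[, 2] <= minb[2, 2] + 1e-12))
  # two minority points, k = 1: synthetics lie on the connecting segment
  X2 <- rbind(matrix(rnorm(20), ncol = 2), c(0, 0), c(1, 1))
  y2 <- rep(c(0L, 1L), c(10, 2))
  set.seed(5)
  out2 <- smote_balance(X2, y2, k_neighbors = 1)
  syn2 <- out2$X[-(seq_len(12)), , drop = FALSE]
  expect_equal(syn2[, 1], syn2[, 2], tolerance = 1e-12)  # on the diagonal
  expect_true(all(syn2[, 1] >= 0 & syn2[, 1] <= 1))
  # balanced input returned unchanged; tiny minority errors
  bal <- smote_balance(X2, rep(c(0L, 1L), 6))
  expect_equal(bal$n_synthetic, 0L)
  expect_error(smote_balance(X2, rep(c(0L, 1L), c(11, 1))), "at least 2")
})

test_that("repeated stratified splits are reproducible and stratified", {
  set.seed(7)
  X <- matrix(rnorm(400), ncol = 2)
  y <- rep(c(0L, 1L), c(160, 40))              # 80/20 imbalance
  cv1 <- repeated_split_cv(majority_classifier(), X, y, n_splits = 8,
                           seed = 42)
  cv2 <- repeated_split_cv(majority_classifier(), X, y, n_splits = 8,
                           seed = 42)
  expect_identical(cv1, cv2)
  # majority baseline: sensitivity 0, specificity 1 on every split
  expect_true(all(cv1$per_split$sensitivity == 0))
  expect_true(all(cv1$per_split$specificity == 1))
  expect_equal(cv1$mean_metrics$specificity, 1)
  # every training part is within 5 points of the full-data class proportion
  spy_props <- new.env(); spy_props$v <- numeric()
  spy <- list(fit = function(X, y) {
    spy_props$v <- c(spy_props$v, mean(y)); 0L
  }, predict = function(fit, X) rep(0L, nrow(X)))
  repeated_split_cv(spy, X, y, n_splits = 10, seed = 9)
  expect_true(all(abs(spy_props$v - 0.2) <= 0.05))
  # SMOTE is applied to the training part only: spy sees balanced classes
  spy_props$v <- numeric()
  repeated_split_cv(spy, X, y, n_splits = 4, smote = TRUE, seed = 9)
  expect_true(all(spy_props$v == 0.5))
  expect_error(repeated_split_cv(majority_classifier(), X, rep(0L, 200)),
               "both classes")
})

test_that("mean metrics are the arithmetic mean of the per-split values", {
  set.seed(12)
  X <- matrix(rnorm(240), ncol = 2)
  y <- as.integer(plogis(X[, 1]) > runif(120))
  cv <- repeated_split_cv(clr_classifier(), X, y, n_splits = 5, seed = 3)
  expect_equal(cv$mean_metrics$f1, mean(cv$per_split$f1))
  expect_equal(cv$mean_metrics$mcc, mean(cv$per_split$mcc))
})

test_that("the Friedman statistic matches hand ranks and the brute oracle", {
  # identical models on every dataset
  same <- matrix(0.7, nrow = 4, ncol = 3)
  expect_equal(friedman_test(same)$Q, 0)
  # k = 2, A beats B on all N datasets: ranks (1, 2), Q = N
  for (N in c(3, 6, 10)) {
    tab <- cbind(A = seq_len(N) + 1, B = seq_len(N))
    ft <- friedman_test(tab)
    expect_equal(ft$Q, N)
    expect_equal(unname(ft$avg_ranks), c(1, 2))
  }
  set.seed(88)
  for (i in 1:10) {
    tab <- matrix(runif(20), nrow = 5, ncol = 4)
    if (i > 5) tab[cbind(1:2, 1:2)] <- tab[cbind(1:2, 3:4)]  # force ties
    ft <- friedman_test(tab)
    oracle <- friedman_oracle(tab)
    expect_equal(unname(ft$avg_ranks), oracle$avg_ranks, tolerance = 1e-9)
    expect_equal(ft$Q, oracle$Q, tolerance = 1e-9)
    expect_equal(ft$F_f, oracle$F_f, tolerance = 1e-9)
    # rank identity: ranks sum to k(k+1)/2 per dataset on average
    expect_equal(sum(ft$avg_ranks), 4 * 5 / 2)
    # cross-check against the standard chi-square implementation; only
    # comparable without ties, since friedman.test applies a tie correction
    if (i <= 5) {
      expect_equal(ft$Q, unname(friedman.test(tab)$statistic),
                   tolerance = 1e-9)
    }
  }
})

test_that("the Nemenyi critical difference follows the tabulated q values", {
  expect_equal(nemenyi_cd(10, 2), 1.960 * sqrt(1 / 10))
  expect_equal(nemenyi_cd(12, 5, alpha = 0.10), 2.459 * sqrt(5 * 6 / 72))
  cds <- sapply(c(5, 10, 20, 50), nemenyi_cd, k = 4)
  expect_true(all(diff(cds) < 0))              # CD shrinks with more datasets
  expect_error(nemenyi_cd(10, 15), "between 2 and")
  expect_error(nemenyi_cd(10, 3, alpha = 0.2), "0.05 or 0.10")
  # pairwise flags are symmetric and irreflexive
  set.seed(14)
  ft <- friedman_test(matrix(runif(40), nrow = 8, ncol = 5))
  expect_true(isSymmetric(ft$pairwise_significant))
  expect_true(all(!diag(ft$pairwise_significant)))
})

test_that("benchmarking composes cross-validation with the rank comparison", {
  d1 <- generate_two_class(preset_dataset_I(seed = 1))
  d2 <- generate_two_class(preset_dataset_II(seed = 2))
  rc <- benchmark_models(
    list(CLR = clr_classifier(), majority = majority_classifier()),
    list(a = list(X = d1$X, y = d1$y), b = list(X = d2$X, y = d2$y)),
    metric = "f1", n_splits = 3, seed = 7)
  expect_s3_class(rc, "rank_comparison")
  expect_equal(dim(rc$score_table), c(2L, 2L))
  expect_equal(sum(rc$avg_ranks), 3)           # k(k+1)/2 with k = 2
  # the informative baseline outranks the majority-class dummy
  expect_lt(rc$avg_ranks[["CLR"]], rc$avg_ranks[["majority"]])
})
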