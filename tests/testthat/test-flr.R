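make_fuzzy_fixture <- function(seed = 1, n = 60, m = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- as.integer(plogis(1.2 * x1 - 0.8 * x2) > runif(n))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  fuzzify_dataset(cbind(x1 = x1, x2 = x2), y,
                  fuzzification_config(m = m, seed = seed))
}

test_that("the fuzzy linear predictor composes TFN add and multiply", {
  z <- tfn(0, 0, 0)
  expect_equal(unclass(linear_predictor(tfn(c(0, 0), c(0, 0), c(0, 0)),
                                        tfn(1, 2, 3))),
               unclass(z))
  # crisp arithmetic passes through exactly
  got <- linear_predictor(tfn(c(1, 0.5), c(1, 0.5), c(1, 0.5)),
                          tfn(2, 2, 2))
  expect_equal(unclass(got), unclass(tfn(2, 2, 2)))
  # grid oracle on a fuzzy product
  got2 <- linear_predictor(tfn(c(0, -1), c(0, 1), c(0, 2)), tfn(1, 2, 3))
  want <- grid_op_oracle(c(-1, 1, 2), c(1, 2, 3), `*`)
  expect_equal(unname(unclass(got2)[1, ]), want, tolerance = 1e-9)
  expect_error(linear_predictor(tfn(0, 0, 0), tfn(1, 2, 3)), "k \\+ 1")
})

test_that("fuzzy probabilities apply the logistic pointwise and stay ordered", {
  expect_equal(unclass(fuzzy_probability(tfn(0, 0, 0))),
               unclass(tfn(0.5, 0.5, 0.5)))
  p <- unclass(fuzzy_probability(tfn(-1, 0, 1)))
  expect_equal(unname(p[1, ]), plogis(c(-1, 0, 1)), tolerance = 1e-12)
  big <- unclass(fuzzy_probability(tfn(-40, -30, -20)))
  expect_true(all(big > 0) && all(diff(big[1, ]) >= 0) && all(big < 1e-8))
  set.seed(3)
  for (i in 1:10) {
    tr <- random_triple(-6, 6)
    pr <- unclass(fuzzy_probability(tfn(tr[1], tr[2], tr[3])))[1, ]
    expect_true(all(pr > 0 & pr < 1) && !is.unsorted(pr))
  }
})

test_that("candidates are sorted triples affinely mapped into the range", {
  cfg <- flr_search_config(I_minus = -2, I_plus = 2, seed = NULL)
  set.seed(21)
  cand <- generate_candidate(cfg, k = 2)
  set.seed(21)
  raw <- matrix(runif(9), ncol = 3, byrow = TRUE)
  want <- -2 + t(apply(raw, 1, sort)) * 4
  expect_equal(unname(unclass(cand)), unname(want))
  m <- unclass(cand)
  expect_true(all(m >= -2 & m <= 2))
  # identity map on [0, 1]
  cfg01 <- flr_search_config(I_minus = 0, I_plus = 1)
  set.seed(4)
  cand01 <- unclass(generate_candidate(cfg01, k = 1))
  set.seed(4)
  raw01 <- matrix(runif(6), ncol = 3, byrow = TRUE)
  expect_equal(unname(cand01), unname(t(apply(raw01, 1, sort))))
  set.seed(9); c1 <- generate_candidate(cfg, 3)
  set.seed(9); c2 <- generate_candidate(cfg, 3)
  expect_identical(c1, c2)
})

test_that("a single-candidate search returns that candidate", {
  fd <- make_fuzzy_fixture(2)
  cfg <- flr_search_config(n_candidates = 1, n_repetitions = 1, seed = 5)
  fit <- flr(fd, cfg)
  set.seed(5)
  want <- generate_candidate(cfg, k = 2)
  expect_equal(unclass(fit$coefficients), unclass(want))
})

test_that("fitting is deterministic and selects the lowest-variation measure", {
  fd <- make_fuzzy_fixture(3)
  cfg <- flr_search_config(n_candidates = 40, n_repetitions = 4, seed = 11)
  f1 <- flr(fd, cfg)
  f2 <- flr(fd, cfg)
  expect_identical(f1, f2)
  expect_true(f1$chosen_measure %in% c("MAE", "MSE", "RMSE"))
  expect_equal(unname(which.min(f1$measure_variations)),
               match(f1$chosen_measure, c("MAE", "MSE", "RMSE")))
  expect_gte(f1$best_error, 0)
  m <- unclass(f1$coefficients)
  expect_true(all(m[, 2] >= cfg$I_minus & m[, 2] <= cfg$I_plus))
  expect_equal(nrow(f1$search_log), 4L)
  expect_error(flr(fd, flr_search_config(n_candidates = 0)), "at least 1")
})

test_that("fitted slope signs recover the generating direction", {
  hits <- sapply(1:100, function(s) {
    d <- generate_two_class(preset_dataset_I(seed = s))
    fd <- fuzzify_dataset(d$X, d$y, fuzzification_config(seed = s))
    fit <- flr(fd, flr_search_config(n_candidates = 200, n_repetitions = 5,
                                     seed = s))
    cf <- coef(fit)
    # X1 lowers the odds of class 1, X2 raises them, by construction
    c(cf$crisp_estimate[2] < 0, cf$crisp_estimate[3] > 0)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("classification against the fuzzy threshold follows the width rule", {
  tau <- fuzzy_threshold(0.4, 0.5, 0.6)
  pr <- classify_fuzzy(tfn(0.2, 0.3, 0.4), tau)
  expect_equal(pr$label, 0L)
  expect_equal(unname(unclass(pr$y_hat)[1, ]), c(-0.2, 0, 0.2))
  expect_equal(pr$d_width, 0.2, ignore_attr = TRUE)
  # expected value exactly at the vertex classifies as 1 ("otherwise")
  at <- classify_fuzzy(tfn(0.5, 0.5, 0.5), tau)
  expect_equal(at$label, 1L)
  # probability equal to the threshold: label 1, width from tau - tau
  eq <- classify_fuzzy(tfn(0.4, 0.5, 0.6), tau)
  expect_equal(eq$label, 1L)
  expect_equal(eq$d_width, tfn_width(tau - tau) / 2, ignore_attr = TRUE)
  full <- classify_fuzzy(tfn(0.2, 0.3, 0.4), tau, width_rule = "full")
  expect_equal(full$d_width, 0.4, ignore_attr = TRUE)
})

test_that("prediction TFNs are symmetric about the crisp label", {
  fd <- make_fuzzy_fixture(6)
  fit <- flr(fd, flr_search_config(n_candidates = 50, n_repetitions = 2,
                                   seed = 2))
  pr <- predict(fit, fd)
  ym <- unclass(pr$y_hat)
  expect_equal(ym[, 3] - ym[, 2], ym[, 2] - ym[, 1])
  expect_equal(ym[, 3] - ym[, 2], pr$d_width)
  expect_equal(ym[, 2], as.double(pr$label))
  pm <- unclass(pr$p_fuzzy)
  expect_true(all(pm > 0 & pm < 1))
  expect_true(all(pr$p_expected > 0 & pr$p_expected < 1))
})

test_that("labels are invariant to row permutation and zero fits label all 1", {
  fd <- make_fuzzy_fixture(8)
  fit <- flr(fd, flr_search_config(n_candidates = 30, n_repetitions = 2,
                                   seed = 3))
  pr <- predict(fit, fd)
  perm <- sample(length(pr$label))
  fd_perm <- fd
  fd_perm$X_lower <- fd$X_lower[perm, ]
  fd_perm$X_vertex <- fd$X_vertex[perm, ]
  fd_perm$X_upper <- fd$X_upper[perm, ]
  fd_perm$Y <- fd$Y[perm]
  fd_perm$y_crisp <- fd$y_crisp[perm]
  pr_perm <- predict(fit, fd_perm)
  expect_equal(pr_perm$label, pr$label[perm])
  # all-zero coefficients give E(P) = 0.5 >= t2 -> all labels 1
  fit0 <- fit
  fit0$coefficients <- tfn(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_true(all(predict(fit0, fd)$label == 1L))
})

test_that("raising coefficient vertices weakly raises expected probabilities", {
  set.seed(13)
  X <- matrix(abs(rnorm(40)), ncol = 2,
              dimnames = list(NULL, c("x1", "x2")))  # nonnegative predictors
  y <- rep(c(0, 1), 10)
  fd <- fuzzify_dataset(X, y, fuzzification_config(seed = 1),
                        standardize = FALSE)
  base <- tfn(c(0, 0.2, 0.1), c(0.1, 0.4, 0.3), c(0.2, 0.6, 0.5))
  up <- tfn(c(0.1, 0.3, 0.2), c(0.2, 0.5, 0.4), c(0.3, 0.7, 0.6))
  fit <- flr(fd, flr_search_config(n_candidates = 1, n_repetitions = 1,
                                   seed = 1))
  fit$coefficients <- base
  e1 <- predict(fit, fd)$p_expected
  fit$coefficients <- up
  e2 <- predict(fit, fd)$p_expected
  expect_true(all(e2 >= e1))
})

test_that("with zero fuzziness and crisp coefficients the model is classical", {
  d <- generate_two_class(preset_dataset_I(seed = 7))
  fd <- fuzzify_dataset(d$X, d$y,
                        fuzzification_config(m = 0,
                                             predictor_mode = "degenerate",
                                             seed = 1))
  beta <- c(0.3, -1.1, 0.8)
  fit <- flr(fd, flr_search_config(n_candidates = 1, n_repetitions = 1,
                                   seed = 1))
  fit$coefficients <- tfn(beta, beta, beta)
  pr <- predict(fit, fd)
  eta <- drop(cbind(1, fd$X_vertex) %*% beta)
  expect_equal(unclass(pr$p_fuzzy)[, 2], plogis(eta), tolerance = 1e-12)
  expect_equal(max(tfn_width(pr$p_fuzzy)), 0)
})

test_that("defuzzified coefficients expose crisp estimates and odds ratios", {
  fd <- make_fuzzy_fixture(4)
  fit <- flr(fd, flr_search_config(n_candidates = 20, n_repetitions = 2,
                                   seed = 9))
  fit$coefficients <- tfn(c(0, 1.507, 1.715), c(0, 1.642, 1.733),
                          c(0, 1.779, 1.974))
  cf <- coef(fit)
  expect_equal(cf$crisp_estimate, c(0, 1.643, 1.807), tolerance = 5e-4)
  expect_equal(cf$odds_ratio[1], 1)
  expect_equal(cf$odds_ratio[2:3], exp(cf$crisp_estimate[2:3]))
})
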