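# Friedman / Nemenyi multi-model comparison over multiple datasets,
# following the standard classifier-comparison methodology (rank per
# dataset, chi-square Friedman statistic, Iman-Davenport F refinement,
# Nemenyi critical difference from the studentized-range table).

# Demsar's two-tailed Nemenyi q_alpha values (q_alpha = studentized range
# statistic / sqrt(2)) for k = 2..10 models.
.nemenyi_q <- list(
  `0.05` = c(NA, 1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102,
             3.164),
  `0.1` = c(NA, 1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855,
            2.920))

#' Nemenyi critical difference
#'
#' The minimum difference in average ranks (over `N` datasets, `k` models)
#' that is significant at level `alpha` after a Friedman test:
#' \eqn{CD = q_\alpha \sqrt{k(k+1)/(6N)}}, with \eqn{q_\alpha} from the
#' studentized-range-based table of the classifier-comparison methodology.
#'
#' @param N Number of datasets (blocks).
#' @param k Number of models, between 2 and 10 (tabulated range).
#' @param alpha Significance level, 0.05 or 0.10.
#' @return The critical difference (positive scalar).
#' @export
nemenyi_cd <- function(N, k, alpha = 0.05) {
  N <- as.integer(N); k <- as.integer(k)
  if (N < 2L) stop("`N` must be at least 2", call. = FALSE)
  key <- as.character(alpha)
  if (!key %in% names(.nemenyi_q)) {
    stop("`alpha` must be 0.05 or 0.10", call. = FALSE)
  }
  qs <- .nemenyi_q[[key]]
  if (k < 2L || k > length(qs)) {
    stop(sprintf("`k` must be between 2 and %d (tabulated range)",
                 length(qs)), call. = FALSE)
  }
  qs[k] * sqrt(k * (k + 1) / (6 * N))
}

#' Friedman test with Nemenyi post hoc comparison
#'
#' Ranks the models within each dataset (larger score = better, rank 1 =
#' best, average ranks on ties), then computes the Friedman statistic
#' \deqn{Q = \frac{12N}{k(k+1)} \left[ \sum_j \bar R_j^2 -
#'   \frac{k(k+1)^2}{4} \right]}
#' and the Iman–Davenport refinement
#' \eqn{F_f = (N-1) Q / (N(k-1) - Q)}, plus the Nemenyi critical difference
#' and the pairwise significance flags \eqn{|\bar R_i - \bar R_j| > CD}.
#'
#' @param score_table Numeric matrix or data frame, datasets as rows and
#'   models as columns; larger values are better.
#' @param alpha Significance level for the Nemenyi critical difference.
#' @return An object of class `"rank_comparison"`: `score_table`,
#'   `avg_ranks`, `Q`, `F_f`, `p_value` (chi-square reference for `Q`),
#'   `CD`, `pairwise_significant` (logical k x k matrix), `N`, `k`,
#'   `alpha`.
#' @examples
#' scores <- cbind(A = c(.9, .8, .95), B = c(.7, .6, .9), C = c(.5, .4, .6))
#' friedman_test(scores)
#' @export
friedman_test <- function(score_table, alpha = 0.05) {
  scores <- as.matrix(score_table)
  storage.mode(scores) <- "double"
  N <- nrow(scores); k <- ncol(scores)
  if (N < 2L || k < 2L) {
    stop("need at least 2 datasets and 2 models", call. = FALSE)
  }
  if (anyNA(scores)) stop("score table contains missing values", call. = FALSE)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("model", seq_len(k))
  }
  ranks <- t(apply(scores, 1L, function(row) rank(-row, ties.method = "average")))
  avg_ranks <- colMeans(ranks)
  Q <- 12 * N / (k * (k + 1)) * (sum(avg_ranks^2) - k * (k + 1)^2 / 4)
  denom <- N * (k - 1) - Q
  F_f <- if (denom <= 0) Inf else (N - 1) * Q / denom
  p_value <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  CD <- nemenyi_cd(N, min(k, 10L), alpha = alpha)
  if (k > 10L) {
    warning("Nemenyi q table covers up to 10 models; CD uses k = 10",
            call. = FALSE)
  }
  diffs <- abs(outer(avg_ranks, avg_ranks, "-"))
  pairwise <- diffs > CD
  diag(pairwise) <- FALSE
  structure(list(score_table = scores, avg_ranks = avg_ranks,
                 Q = Q, F_f = F_f, p_value = p_value, CD = CD,
                 pairwise_significant = pairwise,
                 N = N, k = k, alpha = alpha),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Friedman test over %d datasets, %d models\n", x$N, x$k))
  cat(sprintf("  Q = %.3f, F_f = %.3f, p(chi^2) = %.4g\n",
              x$Q, x$F_f, x$p_value))
  cat(sprintf("  Nemenyi CD (alpha = %g) = %.3f\n", x$alpha, x$CD))
  cat("  average ranks:\n")
  print(round(x$avg_ranks, 3))
  invisible(x)
}

#' Benchmark several classifiers over several datasets
#'
#' Runs [repeated_split_cv()] for every (dataset, model) pair, collects one
#' score per pair (the mean of `metric` over the splits), and compares the
#' models with [friedman_test()]. Datasets and models are supplied as named
#' lists; each dataset is a list with elements `X` and `y`, each model a
#' fit/predict contract (see [flr_classifier()]).
#'
#' @param models Named list of fit/predict contracts.
#' @param datasets Named list of `list(X =, y =)` datasets.
#' @param metric One of `"sensitivity"`, `"specificity"`, `"precision"`,
#'   `"recall"`, `"f1"`, `"mcc"`.
#' @param n_splits,train_fraction,smote,seed Passed to
#'   [repeated_split_cv()]; the seed is varied deterministically per
#'   dataset.
#' @param alpha Passed to [friedman_test()].
#' @return A `"rank_comparison"` (the score table has datasets as rows and
#'   models as columns).
#' @export
benchmark_models <- function(models, datasets,
                             metric = c("f1", "mcc", "sensitivity",
                                        "specificity", "precision", "recall"),
                             n_splits = 10L, train_fraction = 0.7,
                             smote = FALSE, seed = NULL, alpha = 0.05) {
  metric <- match.arg(metric)
  if (length(models) < 2L || length(datasets) < 2L) {
    stop("need at least 2 models and 2 datasets", call. = FALSE)
  }
  scores <- matrix(NA_real_, length(datasets), length(models),
                   dimnames = list(names(datasets), names(models)))
  for (d in seq_along(datasets)) {
    for (m in seq_along(models)) {
      cv <- repeated_split_cv(models[[m]], datasets[[d]]$X, datasets[[d]]$y,
                              n_splits = n_splits,
                              train_fraction = train_fraction,
                              smote = smote,
                              seed = derive_seed(seed, d * 131L + m))
      scores[d, m] <- cv$mean_metrics[[metric]]
    }
  }
  friedman_test(scores, alpha = alpha)
}
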