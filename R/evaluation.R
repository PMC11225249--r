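#' Confusion matrix for binary labels
#'
#' Counts true/false positives and negatives with class 1 as the positive
#' class.
#'
#' @param y_true,y_pred Equal-length vectors of 0/1 labels.
#' @return An object of class `"confusion_matrix"`: list with integer
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_matrix")
}

#' @rdname confusion
#' @param TP,TN,FP,FN Nonnegative integer counts, for building a confusion
#'   matrix directly (e.g. from a published table).
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(lapply(counts, as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (positive class = 1)\n")
  cat(sprintf("            pred 0  pred 1\n"))
  cat(sprintf("  actual 0  %6d  %6d\n", x$TN, x$FP))
  cat(sprintf("  actual 1  %6d  %6d\n", x$FN, x$TP))
  invisible(x)
}

#' Classification performance measures
#'
#' Computes sensitivity \eqn{TP/(TP+FN)}, specificity \eqn{TN/(TN+FP)},
#' precision \eqn{TP/(TP+FP)}, recall (= sensitivity), F1 (harmonic mean of
#' precision and recall), and Matthews correlation coefficient
#' \eqn{\mathrm{MCC} = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#' A metric whose denominator is zero is returned as 0 with a warning —
#' the convention under which an all-negative classifier on imbalanced data
#' scores sensitivity 0 rather than NaN.
#'
#' @param cm A [confusion()] or [confusion_counts()] object.
#' @return An object of class `"metric_set"`: named list with `sensitivity`,
#'   `specificity`, `precision`, `recall`, `f1`, `mcc`.
#' @examples
#' classification_metrics(confusion_counts(TP = 4, TN = 82, FP = 2, FN = 11))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_div(cm$TP, cm$TP + cm$FN, "sensitivity")
  spec <- safe_div(cm$TN, cm$TN + cm$FP, "specificity")
  prec <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  rec <- sens
  f1 <- if (prec + rec == 0) {
    warning("F1 undefined (zero denominator); returning 0", call. = FALSE)
    0
  } else 2 * prec * rec / (prec + rec)
  denom2 <- as.double(cm$TP + cm$FP) * (cm$TP + cm$FN) *
    (cm$TN + cm$FP) * (cm$TN + cm$FN)
  mcc <- if (denom2 == 0) {
    warning("MCC undefined (zero denominator factor); returning 0",
            call. = FALSE)
    0
  } else {
    (as.double(cm$TP) * cm$TN - as.double(cm$FP) * cm$FN) / sqrt(denom2)
  }
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 recall = rec, f1 = f1, mcc = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.3f  specificity %.3f  precision %.3f  ",
                     "recall %.3f  F1 %.3f  MCC %.3f\n"),
              x$sensitivity, x$specificity, x$precision, x$recall,
              x$f1, x$mcc))
  invisible(x)
}

#' SMOTE minority oversampling
#'
#' Balances a binary dataset by synthetic minority oversampling: each
#' synthetic observation is a convex combination \eqn{x + u (x_{nn} - x)},
#' \eqn{u \sim \mathrm{Uniform}(0, 1)}, of a random minority point and one
#' of its `k_neighbors` nearest minority neighbours (Euclidean distance).
#' Already balanced data are returned unchanged. Intended for training
#' partitions only; the cross-validation harness applies it there.
#'
#' @param X Numeric predictor matrix.
#' @param y 0/1 labels; the minority class must have more than one member.
#' @param k_neighbors Number of minority nearest neighbours considered
#'   (default 5, capped at minority size minus one).
#' @return List with the augmented `X`, `y`, and `n_synthetic`.
#' @export
smote_balance <- function(X, y, k_neighbors = 5L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == n0) return(list(X = X, y = y, n_synthetic = 0L))
  minority <- if (n1 < n0) 1L else 0L
  Xm <- X[y == minority, , drop = FALSE]
  n_min <- nrow(Xm)
  if (n_min <= 1L) {
    stop(sprintf("minority class has %d member(s); SMOTE needs at least 2",
                 n_min), call. = FALSE)
  }
  k_neighbors <- min(as.integer(k_neighbors), n_min - 1L)
  if (k_neighbors < 1L) stop("`k_neighbors` must be at least 1", call. = FALSE)
  dmat <- as.matrix(stats::dist(Xm))
  diag(dmat) <- Inf
  nn_idx <- do.call(rbind, lapply(seq_len(n_min), function(i) {
    order(dmat[i, ])[seq_len(k_neighbors)]
  }))
  n_needed <- abs(n0 - n1)
  base <- sample.int(n_min, n_needed, replace = TRUE)
  pick <- nn_idx[cbind(base, sample.int(k_neighbors, n_needed, replace = TRUE))]
  u <- stats::runif(n_needed)
  X_syn <- Xm[base, , drop = FALSE] +
    u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  list(X = rbind(X, X_syn),
       y = c(y, rep(minority, n_needed)),
       n_synthetic = n_needed)
}

#' Repeated stratified split cross-validation
#'
#' Evaluates a classifier by `n_splits` repeated stratified random
#' train/test partitions (default 10 splits at a 70/30 ratio). Stratification
#' draws the training fraction within each class, so every training set
#' contains both classes at (close to) the full-data proportions. When
#' `smote = TRUE`, [smote_balance()] is applied to the training part only.
#' Deterministic given `seed`.
#'
#' The classifier is supplied through a fit/predict contract: a list with
#' `fit(X, y)` returning a fitted object and `predict(fit, X)` returning 0/1
#' labels — see [flr_classifier()] and [clr_classifier()]; any external
#' model can be plugged in the same way.
#'
#' @param model A fit/predict contract list.
#' @param X Numeric predictor matrix.
#' @param y 0/1 labels with both classes.
#' @param n_splits Number of repeated splits (default 10).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param smote Apply SMOTE to each training part? Default `FALSE`.
#' @param seed Integer seed for the partitions (and SMOTE draws).
#' @return An object of class `"cv_result"`: `per_split` data frame
#'   (split, confusion counts and metrics), `mean_metrics` (a
#'   `"metric_set"`), and the echoed configuration.
#' @export
repeated_split_cv <- function(model, X, y, n_splits = 10L,
                              train_fraction = 0.7, smote = FALSE,
                              seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n_splits <- as.integer(n_splits)
  if (n_splits < 1L) stop("`n_splits` must be at least 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("both classes required in `y`", call. = FALSE)
  }
  idx0 <- which(y == 0L); idx1 <- which(y == 1L)
  n_tr0 <- round(length(idx0) * train_fraction)
  n_tr1 <- round(length(idx1) * train_fraction)
  n_tr0 <- min(max(n_tr0, 1L), length(idx0) - 1L)
  n_tr1 <- min(max(n_tr1, 1L), length(idx1) - 1L)
  if (n_tr0 < 1L || n_tr1 < 1L) {
    stop("too few observations per class to stratify the split",
         call. = FALSE)
  }
  with_seed(seed, {
    rows <- vector("list", n_splits)
    for (s in seq_len(n_splits)) {
      tr <- c(sample(idx0, n_tr0), sample(idx1, n_tr1))
      te <- setdiff(seq_along(y), tr)
      X_tr <- X[tr, , drop = FALSE]; y_tr <- y[tr]
      if (isTRUE(smote)) {
        bal <- smote_balance(X_tr, y_tr)
        X_tr <- bal$X; y_tr <- bal$y
      }
      fitted <- model$fit(X_tr, y_tr)
      pred <- model$predict(fitted, X[te, , drop = FALSE])
      cm <- confusion(y[te], pred)
      ms <- suppressWarnings(classification_metrics(cm))
      rows[[s]] <- data.frame(split = s, TP = cm$TP, TN = cm$TN,
                              FP = cm$FP, FN = cm$FN,
                              sensitivity = ms$sensitivity,
                              specificity = ms$specificity,
                              precision = ms$precision, recall = ms$recall,
                              f1 = ms$f1, mcc = ms$mcc)
    }
    per_split <- do.call(rbind, rows)
    mean_metrics <- structure(as.list(colMeans(
      per_split[, c("sensitivity", "specificity", "precision", "recall",
                    "f1", "mcc")])), class = "metric_set")
    structure(list(per_split = per_split, mean_metrics = mean_metrics,
                   n_splits = n_splits, train_fraction = train_fraction,
                   smote = isTRUE(smote), seed = seed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d stratified %d/%d splits%s\n",
              x$n_splits, round(100 * x$train_fraction),
              round(100 * (1 - x$train_fraction)),
              if (x$smote) " with SMOTE" else ""))
  cat("  mean metrics: ")
  print(x$mean_metrics)
  invisible(x)
}

#' Classifier contracts for the cross-validation harness
#'
#' `flr_classifier()` wraps the fuzzy logistic regression
#' (fuzzify, [flr()], [predict.flr()]) and `clr_classifier()` wraps the
#' classical-logistic baseline ([irls_fit()], [clr_predict()]) into the
#' fit/predict contract consumed by [repeated_split_cv()] and
#' [benchmark_models()].
#'
#' @param fuzz_cfg A [fuzzification_config()].
#' @param search_cfg A [flr_search_config()].
#' @param tau A [fuzzy_threshold()].
#' @param seed Seed used for fuzzification and search inside each fit.
#' @return A list with elements `fit` and `predict`.
#' @export
flr_classifier <- function(fuzz_cfg = fuzzification_config(),
                           search_cfg = flr_search_config(),
                           tau = fuzzy_threshold(), seed = NULL) {
  list(
    fit = function(X, y) {
      fc <- fuzz_cfg; fc$seed <- seed
      sc <- search_cfg; sc$seed <- derive_seed(seed, 1L)
      flr(fuzzify_dataset(X, y, fc), sc)
    },
    predict = function(fit, X) {
      predict(fit, X, tau = tau, seed = derive_seed(seed, 2L))$label
    })
}

#' @rdname flr_classifier
#' @param max_iter,tol,cutoff Passed to [irls_fit()] / [clr_predict()].
#' @export
clr_classifier <- function(max_iter = 100L, tol = 1e-8, cutoff = 0.5) {
  list(
    fit = function(X, y) irls_fit(X, y, max_iter = max_iter, tol = tol),
    predict = function(fit, X) clr_predict(fit, X, cutoff = cutoff))
}
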