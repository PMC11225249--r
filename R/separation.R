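#' Logistic regression by IRLS with coefficient trajectory
#'
#' Fits a classical logistic regression by iteratively reweighted least
#' squares, recording the coefficient vector after every iteration. Under
#' complete (or quasi-complete) separation the maximum likelihood estimates
#' diverge, so the per-iteration trajectory — not the converged value — is
#' the diagnostic: the fit never raises on divergence, it simply stops at
#' `max_iter` with `converged = FALSE`.
#'
#' Predictors are standardized internally (zero mean, unit variance) by
#' default so that the divergence threshold used by [detect_separation()] is
#' scale-free; the recorded trajectory is on the standardized scale.
#'
#' @param X Numeric predictor matrix (one column per predictor).
#' @param y 0/1 response with both classes present.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Convergence tolerance on the max absolute coefficient change
#'   (default 1e-8).
#' @param standardize Standardize predictors first? Default `TRUE`.
#' @return An object of class `"irls_trajectory"`: `estimates` (iterations
#'   x (k+1) matrix, intercept first), `converged`, `n_iter`,
#'   `deviance_path`, `coefficients` (final iterate), `center`, `scale`,
#'   `column_names`.
#' @export
irls_fit <- function(X, y, max_iter = 100L, tol = 1e-8, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.double(y)
  if (length(y) != nrow(X)) stop("`y` must match rows of `X`", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("response must be 0/1", call. = FALSE)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0L)) {
    stop(sprintf("both classes required: %d zeros and %d ones found",
                 tab[["0"]], tab[["1"]]), call. = FALSE)
  }
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")
  } else {
    center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X)); Xs <- X
  }
  D <- cbind(`(Intercept)` = 1, Xs)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1L):ncol(D)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  beta <- rep(0, ncol(D))
  est <- matrix(NA_real_, max_iter, ncol(D),
                dimnames = list(NULL, colnames(D)))
  dev <- rep(NA_real_, max_iter)
  converged <- FALSE
  n_iter <- 0L
  eps <- 1e-10
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), eps)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(D, z, w)
    beta_new <- fit$coefficients
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    n_iter <- it
    est[it, ] <- beta
    pc <- pmin(pmax(stats::plogis(drop(D %*% beta)), eps), 1 - eps)
    dev[it] <- -2 * sum(y * log(pc) + (1 - y) * log(1 - pc))
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(estimates = est[seq_len(n_iter), , drop = FALSE],
                 converged = converged, n_iter = n_iter,
                 deviance_path = dev[seq_len(n_iter)],
                 coefficients = beta, center = center, scale = scale_,
                 column_names = nms, tol = tol),
            class = "irls_trajectory")
}

#' @export
print.irls_trajectory <- function(x, ...) {
  cat(sprintf("IRLS logistic fit: %d iteration(s), %s\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("  final estimates (standardized scale):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Detect complete separation from an IRLS trajectory
#'
#' Under complete or quasi-complete separation the maximum likelihood
#' estimate does not exist, so the optimizer cannot converge: estimates
#' drift towards infinity across iterations. A coefficient is therefore
#' flagged only when the fit failed to converge and either its final
#' estimate is large on the standardized scale (`|estimate| > threshold`)
#' or its magnitude grew in each of the last `growth_window` iterations —
#' the numeric analogue of watching maximum likelihood estimates drift to
#' infinity. A converged fit has a finite maximum likelihood estimate and
#' is never flagged, however large its coefficients: near-separated samples
#' with a sliver of class overlap legitimately produce big finite estimates.
#'
#' @param traj An [irls_fit()] result.
#' @param threshold Divergence threshold on the standardized scale
#'   (default 10).
#' @param growth_window Number of trailing iterations that must each show
#'   magnitude growth for a non-converged fit to be flagged (default 5).
#' @return An object of class `"separation_report"`: `flagged_predictors`
#'   (data frame with `name`, `final_estimate`, `growth_flag`), `verdict`
#'   (`"separation"` or `"no_separation"`), `threshold_used`, `converged`.
#' @export
detect_separation <- function(traj, threshold = 10, growth_window = 5L) {
  stopifnot(inherits(traj, "irls_trajectory"))
  est <- traj$estimates
  if (nrow(est) == 0L) stop("empty trajectory", call. = FALSE)
  final <- est[nrow(est), ]
  growth <- rep(FALSE, ncol(est))
  if (!traj$converged && nrow(est) > growth_window) {
    tail_iters <- (nrow(est) - growth_window):nrow(est)
    mags <- abs(est[tail_iters, , drop = FALSE])
    growth <- apply(mags, 2L, function(v) all(diff(v) > 0))
  }
  flag <- !traj$converged & (abs(final) > threshold | growth)
  flagged <- data.frame(name = colnames(est)[flag],
                        final_estimate = unname(final[flag]),
                        growth_flag = unname(growth[flag]),
                        row.names = NULL)
  structure(list(flagged_predictors = flagged,
                 verdict = if (nrow(flagged)) "separation" else "no_separation",
                 threshold_used = threshold,
                 growth_window = growth_window,
                 converged = traj$converged),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("Separation verdict: %s (threshold %g)\n",
              x$verdict, x$threshold_used))
  if (nrow(x$flagged_predictors)) {
    for (i in seq_len(nrow(x$flagged_predictors))) {
      cat(sprintf("  %s: final estimate %.3f%s\n",
                  x$flagged_predictors$name[i],
                  x$flagged_predictors$final_estimate[i],
                  if (x$flagged_predictors$growth_flag[i])
                    " (monotone growth, no convergence)" else ""))
    }
  }
  invisible(x)
}

#' Crisp labels from a classical logistic fit
#'
#' The classical-logistic baseline classifier: applies the (final-iterate)
#' coefficients of an [irls_fit()] to new data, on the training
#' standardization, and labels an observation 1 when its fitted probability
#' is at least `cutoff`.
#'
#' @param traj An [irls_fit()] result.
#' @param X Numeric predictor matrix with the same columns as the fit.
#' @param cutoff Probability cutoff (default 0.5); probability equal to the
#'   cutoff is classified 1.
#' @return Integer vector of 0/1 labels.
#' @export
clr_predict <- function(traj, X, cutoff = 0.5) {
  stopifnot(inherits(traj, "irls_trajectory"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(traj$center)) {
    stop(sprintf("fit has %d predictors but data has %d columns",
                 length(traj$center), ncol(X)), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, traj$center, "-"), 2L, traj$scale, "/")
  eta <- drop(cbind(1, Xs) %*% traj$coefficients)
  as.integer(stats::plogis(eta) >= cutoff)
}
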