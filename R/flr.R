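#' Coefficient search settings for fuzzy logistic regression
#'
#' The fuzzy coefficients are estimated by bounded random search: candidate
#' TFN coefficient vectors are drawn uniformly inside the pre-defined range
#' \eqn{[I^-, I^+]}, evaluated against the observed fuzzy responses with the
#' MAE, MSE and RMSE optimization measures, and the search is repeated to
#' obtain a sample of best measure values from which the most stable measure
#' is selected (see [flr()]).
#'
#' @param I_minus,I_plus Lower/upper bound of the coefficient search range.
#'   Defaults \eqn{[-2, 2]}, consistent with crisp estimates on standardized
#'   clinical predictors clustering in roughly \eqn{[-1.6, 1.9]}.
#' @param n_candidates Candidate coefficient vectors drawn per repetition.
#' @param n_repetitions Independent repetitions used to measure the
#'   stability of each optimization measure.
#' @param error_kind Retained for completeness: `"absolute"` corresponds to
#'   MAE; MSE/RMSE are always computed alongside.
#' @param error_points Compare predicted and observed TFNs on `"all"` three
#'   defining points (default) or on the `"vertex"` only.
#' @param seed Integer seed; the whole search is deterministic given it.
#' @return An object of class `"flr_search_config"`.
#' @export
flr_search_config <- function(I_minus = -2, I_plus = 2,
                              n_candidates = 500, n_repetitions = 20,
                              error_kind = c("absolute", "squared"),
                              error_points = c("all", "vertex"),
                              seed = NULL) {
  error_kind <- match.arg(error_kind)
  error_points <- match.arg(error_points)
  stopifnot_scalar_number(I_minus, "I_minus")
  stopifnot_scalar_number(I_plus, "I_plus")
  if (I_minus >= I_plus) stop("`I_minus` must be below `I_plus`", call. = FALSE)
  n_candidates <- as.integer(n_candidates)
  n_repetitions <- as.integer(n_repetitions)
  if (n_candidates < 1L || n_repetitions < 1L) {
    stop("`n_candidates` and `n_repetitions` must be at least 1", call. = FALSE)
  }
  structure(list(I_minus = I_minus, I_plus = I_plus,
                 n_candidates = n_candidates, n_repetitions = n_repetitions,
                 error_kind = error_kind, error_points = error_points,
                 seed = seed),
            class = "flr_search_config")
}

#' Fuzzy classification threshold
#'
#' The TFN threshold \eqn{\bar\tau = (t_1, t_2, t_3)} on the probability
#' scale against which fuzzy probabilities are classified. The default
#' \eqn{(0.4, 0.5, 0.6)} is a symmetric fuzzy analogue of the crisp 0.5
#' cutoff.
#'
#' @param t1,t2,t3 Ordered reals in \[0, 1\].
#' @return An object of classes `"fuzzy_threshold"` and `"tfn"`.
#' @export
fuzzy_threshold <- function(t1 = 0.4, t2 = 0.5, t3 = 0.6) {
  if (t1 < 0 || t3 > 1) {
    stop("threshold points must lie in [0, 1]", call. = FALSE)
  }
  out <- tfn(t1, t2, t3)
  class(out) <- c("fuzzy_threshold", class(out))
  out
}

#' Fuzzy linear predictor
#'
#' Computes \eqn{\bar\eta = \bar\beta_0 \oplus \sum_j \bar\beta_j \otimes
#' \bar X_j} with TFN addition and re-triangularized multiplication.
#'
#' @param coefficients A [tfn] vector of length \eqn{k + 1}: intercept first,
#'   then one coefficient per predictor.
#' @param row A [tfn] vector of length \eqn{k} holding one observation's
#'   fuzzy predictor values.
#' @return A single [tfn].
#' @export
linear_predictor <- function(coefficients, row) {
  coefficients <- as_tfn(coefficients)
  row <- as_tfn(row)
  if (length(coefficients) != length(row) + 1L) {
    stop(sprintf("%d coefficients cannot multiply %d predictors (need k + 1)",
                 length(coefficients), length(row)), call. = FALSE)
  }
  eta <- coefficients[1L]
  for (j in seq_len(length(row))) {
    eta <- eta + coefficients[j + 1L] * row[j]
  }
  eta
}

#' Fuzzy success probability
#'
#' Inverts the fuzzy logit pointwise: \eqn{\bar P = (\sigma(\eta_1),
#' \sigma(\eta_2), \sigma(\eta_3))} with \eqn{\sigma} the standard logistic
#' function. Because \eqn{\sigma} is strictly increasing the TFN ordering is
#' preserved and all points lie in \eqn{(0, 1)}.
#'
#' @param eta A [tfn] vector of linear predictors.
#' @return A [tfn] vector of fuzzy probabilities.
#' @export
fuzzy_probability <- function(eta) {
  m <- unclass(as_tfn(eta))
  tfn(stats::plogis(m[, 1L]), stats::plogis(m[, 2L]), stats::plogis(m[, 3L]))
}

#' Draw one candidate TFN coefficient vector
#'
#' Draws \eqn{3(k+1)} values uniformly on \[0, 1\], groups them into
#' consecutive triples, sorts each triple, and maps \[0, 1\] affinely onto
#' the search range \eqn{[I^-, I^+]}; each sorted triple becomes one TFN
#' coefficient (intercept first).
#'
#' @param cfg A [flr_search_config()].
#' @param k Number of predictors.
#' @return A [tfn] vector of length `k + 1` with supports inside the range.
#' @export
generate_candidate <- function(cfg, k) {
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  raw <- matrix(stats::runif(3L * (k + 1L)), ncol = 3L, byrow = TRUE)
  sorted <- t(apply(raw, 1L, sort))
  mapped <- cfg$I_minus + sorted * (cfg$I_plus - cfg$I_minus)
  tfn(mapped[, 1L], mapped[, 2L], mapped[, 3L])
}

# Draw a block of candidates as an n x 3(k+1) matrix of already-sorted,
# range-mapped triples: row = candidate, triple j = coefficient j.
draw_candidate_block <- function(cfg, k, n) {
  p <- 3L * (k + 1L)
  raw <- matrix(stats::runif(n * p), nrow = n, ncol = p, byrow = TRUE)
  for (j in seq_len(k + 1L)) {
    idx <- (3L * (j - 1L) + 1L):(3L * j)
    block <- raw[, idx, drop = FALSE]
    lo <- pmin(block[, 1L], block[, 2L], block[, 3L])
    hi <- pmax(block[, 1L], block[, 2L], block[, 3L])
    mid <- block[, 1L] + block[, 2L] + block[, 3L] - lo - hi
    raw[, idx] <- cbind(lo, mid, hi)
  }
  cfg$I_minus + raw * (cfg$I_plus - cfg$I_minus)
}

# Fuzzy probabilities for every candidate in a block, vectorized over
# candidates: returns list(lo, mid, hi), each an N x n matrix.
block_probabilities <- function(cand, data) {
  k <- ncol(data$X_vertex)
  n <- nrow(cand)
  N <- nrow(data$X_vertex)
  eta_lo <- matrix(cand[, 1L], N, n, byrow = TRUE)
  eta_mid <- matrix(cand[, 2L], N, n, byrow = TRUE)
  eta_hi <- matrix(cand[, 3L], N, n, byrow = TRUE)
  for (j in seq_len(k)) {
    b1 <- cand[, 3L * j + 1L]; b2 <- cand[, 3L * j + 2L]; b3 <- cand[, 3L * j + 3L]
    x1 <- data$X_lower[, j]; x2 <- data$X_vertex[, j]; x3 <- data$X_upper[, j]
    p11 <- outer(x1, b1); p13 <- outer(x1, b3)
    p31 <- outer(x3, b1); p33 <- outer(x3, b3)
    eta_lo <- eta_lo + pmin(p11, p13, p31, p33)
    eta_hi <- eta_hi + pmax(p11, p13, p31, p33)
    eta_mid <- eta_mid + outer(x2, b2)
  }
  list(lo = stats::plogis(eta_lo), mid = stats::plogis(eta_mid),
       hi = stats::plogis(eta_hi))
}

# Per-candidate MAE / MSE / RMSE against the observed fuzzy responses.
block_errors <- function(prob, data, points) {
  ym <- unclass(data$Y)
  if (points == "vertex") {
    d2 <- prob$mid - ym[, 2L]
    mae <- colMeans(abs(d2))
    mse <- colMeans(d2 * d2)
  } else {
    d1 <- prob$lo - ym[, 1L]; d2 <- prob$mid - ym[, 2L]; d3 <- prob$hi - ym[, 3L]
    mae <- colMeans((abs(d1) + abs(d2) + abs(d3)) / 3)
    mse <- colMeans((d1 * d1 + d2 * d2 + d3 * d3) / 3)
  }
  cbind(MAE = mae, MSE = mse, RMSE = sqrt(mse))
}

#' Fit a fuzzy logistic regression by bounded random search
#'
#' For each of `n_repetitions` repetitions, `n_candidates` TFN coefficient
#' vectors are drawn inside \eqn{[I^-, I^+]} (see [generate_candidate()]);
#' each candidate's fuzzy probabilities \eqn{\bar P_i} are compared with the
#' observed fuzzified responses \eqn{\bar Y_i} through the MAE, MSE and RMSE
#' optimization measures. Across repetitions the best value of each measure
#' forms a sample; the measure with the lowest coefficient of variation
#' (dispersion relative to scale, so the three measures are comparable) is
#' chosen, and the candidate minimizing the chosen measure over all
#' repetitions becomes the fitted coefficient vector. Ties are broken by
#' candidate order. Deterministic given `cfg$seed`.
#'
#' @param data A [fuzzify_dataset()] result with both classes present.
#' @param cfg A [flr_search_config()].
#' @return An object of class `"flr"` with elements `coefficients` (a [tfn]
#'   of length k + 1, intercept first), `chosen_measure`,
#'   `measure_variations`, `best_error`, `best_errors` (per measure),
#'   `search_log` (per-repetition best values), `column_names`, and the
#'   echoed `config` plus the training standardization.
#' @examples
#' spec <- preset_dataset_I(seed = 1)
#' d <- generate_two_class(spec)
#' fd <- fuzzify_dataset(d$X, d$y, fuzzification_config(seed = 1))
#' fit <- flr(fd, flr_search_config(n_candidates = 50, n_repetitions = 3,
#'                                  seed = 1))
#' coef(fit)
#' @export
flr <- function(data, cfg = flr_search_config()) {
  stopifnot(inherits(data, "fuzzy_dataset"))
  if (is.null(data$y_crisp)) {
    stop("`data` has no response; fit requires a fuzzified response",
         call. = FALSE)
  }
  tab <- table(factor(data$y_crisp, levels = c(0, 1)))
  if (any(tab == 0L)) {
    stop(sprintf("both classes required: %d zeros and %d ones found",
                 tab[["0"]], tab[["1"]]), call. = FALSE)
  }
  k <- ncol(data$X_vertex)
  with_seed(cfg$seed, {
    best_per_rep <- matrix(NA_real_, cfg$n_repetitions, 3L,
                           dimnames = list(NULL, c("MAE", "MSE", "RMSE")))
    best_cand <- vector("list", 3L)        # best candidate per measure so far
    best_val <- rep(Inf, 3L)
    for (rep_i in seq_len(cfg$n_repetitions)) {
      cand <- draw_candidate_block(cfg, k, cfg$n_candidates)
      prob <- block_probabilities(cand, data)
      err <- block_errors(prob, data, cfg$error_points)
      best_per_rep[rep_i, ] <- apply(err, 2L, min)
      for (m in 1:3) {
        i <- which.min(err[, m])           # which.min takes the first tie
        if (err[i, m] < best_val[m]) {
          best_val[m] <- err[i, m]
          best_cand[[m]] <- cand[i, ]
        }
      }
    }
    cv <- apply(best_per_rep, 2L, function(v) {
      if (length(v) < 2L) return(0)
      mu <- mean(v)
      if (mu == 0) return(0)
      stats::sd(v) / mu
    })
    chosen <- which.min(cv)                # ties -> MAE, MSE, RMSE order
    flat <- best_cand[[chosen]]
    coefs <- tfn(flat[seq(1L, 3L * (k + 1L), by = 3L)],
                 flat[seq(2L, 3L * (k + 1L), by = 3L)],
                 flat[seq(3L, 3L * (k + 1L), by = 3L)])
    structure(list(coefficients = coefs,
                   chosen_measure = colnames(best_per_rep)[chosen],
                   measure_variations = cv,
                   best_error = best_val[chosen],
                   best_errors = stats::setNames(best_val,
                                                 colnames(best_per_rep)),
                   search_log = as.data.frame(cbind(repetition =
                     seq_len(cfg$n_repetitions), best_per_rep)),
                   column_names = data$column_names,
                   center = data$center, scale = data$scale,
                   fuzzification = data$config, config = cfg),
              class = "flr")
  })
}

#' @export
print.flr <- function(x, ...) {
  cat("Fuzzy logistic regression fit\n")
  cat(sprintf("  optimization measure: %s (best %.5f)\n",
              x$chosen_measure, x$best_error))
  cat(sprintf("  measure variation (CV): MAE %.4f, MSE %.4f, RMSE %.4f\n",
              x$measure_variations[1L], x$measure_variations[2L],
              x$measure_variations[3L]))
  nms <- c("(Intercept)", x$column_names)
  lab <- format(x$coefficients)
  for (i in seq_along(nms)) cat(sprintf("  %-14s %s\n", nms[i], lab[i]))
  invisible(x)
}

#' Defuzzified coefficients and odds ratios
#'
#' Center-of-gravity defuzzification collapses each TFN coefficient
#' \eqn{\bar\beta_j} to the crisp estimate \eqn{\beta_j = (b_1+b_2+b_3)/3};
#' the odds ratio is \eqn{\theta_j = \exp(\beta_j)}, interpreted as in
#' classical logistic regression (on the standardized predictor scale).
#'
#' @param object A fitted [flr()] model.
#' @param ... Unused.
#' @return A data frame with columns `term`, `a1`, `a2`, `a3`,
#'   `crisp_estimate`, `odds_ratio`.
#' @export
coef.flr <- function(object, ...) {
  m <- unclass(object$coefficients)
  crisp <- defuzzify_cog(object$coefficients)
  data.frame(term = c("(Intercept)", object$column_names),
             a1 = m[, 1L], a2 = m[, 2L], a3 = m[, 3L],
             crisp_estimate = crisp,
             odds_ratio = exp(crisp),
             row.names = NULL)
}

#' Classify fuzzy probabilities against a fuzzy threshold
#'
#' For each fuzzy probability \eqn{\bar P}: the expected value
#' \eqn{E(\bar P)} (Dubois–Prade mean) is compared with the threshold vertex
#' \eqn{t_2}; the predicted vertex is \eqn{\hat y_2 = 0} if
#' \eqn{E(\bar P) < t_2} and 1 otherwise. The fuzzy difference
#' \eqn{D = \bar P \ominus \bar\tau} supplies the prediction's fuzziness:
#' with the default `width_rule = "half"`, \eqn{w(D)} is half the support
#' width of \eqn{D} so that the prediction TFN
#' \eqn{(\hat y_2 - w,\ \hat y_2,\ \hat y_2 + w)} has total support equal to
#' the support of \eqn{D}; `"full"` uses the full support width.
#'
#' @param p_fuzzy A [tfn] vector of fuzzy probabilities.
#' @param tau A [fuzzy_threshold()].
#' @param width_rule `"half"` (default) or `"full"`.
#' @return An object of class `"fuzzy_prediction"`: list with `p_fuzzy`,
#'   `p_expected`, `d_fuzzy`, `d_width`, `y_hat` (a [tfn]), and integer
#'   `label`.
#' @export
classify_fuzzy <- function(p_fuzzy, tau = fuzzy_threshold(),
                           width_rule = c("half", "full")) {
  width_rule <- match.arg(width_rule)
  p_fuzzy <- as_tfn(p_fuzzy)
  e_p <- expected_value(p_fuzzy)
  t2 <- unclass(tau)[1L, 2L]
  label <- as.integer(e_p >= t2)           # equality -> 1 ("otherwise")
  d <- p_fuzzy - tfn(unclass(tau)[1L, 1L], t2, unclass(tau)[1L, 3L])
  w <- tfn_width(d)
  if (width_rule == "half") w <- w / 2
  y_hat <- tfn(label - w, label, label + w)
  structure(list(p_fuzzy = p_fuzzy, p_expected = e_p, d_fuzzy = d,
                 d_width = w, y_hat = y_hat, label = label,
                 tau = tau, width_rule = width_rule),
            class = "fuzzy_prediction")
}

#' @export
print.fuzzy_prediction <- function(x, ...) {
  n <- length(x$label)
  cat(sprintf("<fuzzy_prediction[%d]> labels: %d zeros, %d ones\n",
              n, sum(x$label == 0L), sum(x$label == 1L)))
  invisible(x)
}

#' @export
as.data.frame.fuzzy_prediction <- function(x, ...) {
  pm <- unclass(x$p_fuzzy)
  ym <- unclass(x$y_hat)
  data.frame(p1 = pm[, 1L], p2 = pm[, 2L], p3 = pm[, 3L],
             E_P = x$p_expected,
             y_hat_1 = ym[, 1L], y_hat_2 = ym[, 2L], y_hat_3 = ym[, 3L],
             label = x$label)
}

#' Predict from a fitted fuzzy logistic regression
#'
#' Composes the fuzzy linear predictor, the logistic transform and the fuzzy
#' threshold classification for every observation of a fuzzy dataset.
#'
#' @param object A fitted [flr()] model.
#' @param data A `"fuzzy_dataset"` with the same predictors. A plain numeric
#'   matrix/data frame of crisp predictors is also accepted and is
#'   standardized and fuzzified on the training scale (see
#'   [fuzzify_newdata()]).
#' @param tau A [fuzzy_threshold()].
#' @param width_rule Passed to [classify_fuzzy()].
#' @param seed Seed for fuzzifying crisp `data` (ignored for fuzzy input).
#' @param ... Unused.
#' @return A `"fuzzy_prediction"` object (see [classify_fuzzy()]).
#' @export
predict.flr <- function(object, data, tau = fuzzy_threshold(),
                        width_rule = c("half", "full"), seed = NULL, ...) {
  width_rule <- match.arg(width_rule)
  if (!inherits(data, "fuzzy_dataset")) {
    template <- list(center = object$center, scale = object$scale,
                     config = object$fuzzification,
                     column_names = object$column_names)
    class(template) <- "fuzzy_dataset"
    data <- fuzzify_newdata(template, data, seed = seed)
  }
  if (ncol(data$X_vertex) + 1L != length(object$coefficients)) {
    stop(sprintf("model has %d coefficients but data has %d predictors",
                 length(object$coefficients), ncol(data$X_vertex)),
         call. = FALSE)
  }
  cm <- unclass(object$coefficients)
  cand <- matrix(t(cm), nrow = 1L)         # flat (a1,a2,a3) per coefficient
  prob <- block_probabilities(cand, data)
  p <- tfn(prob$lo[, 1L], prob$mid[, 1L], prob$hi[, 1L])
  classify_fuzzy(p, tau = tau, width_rule = width_rule)
}
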