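#' Specification of a two-predictor imbalanced/separated dataset
#'
#' Describes a two-predictor binary dataset drawn from class-conditional
#' normal distributions, with controlled class imbalance and a controlled
#' degree of separation. Separation is induced through the second predictor
#' by making the positive class markedly more homogeneous
#' (\eqn{\mathrm{Var}(X_2 \mid Y{=}1) = \rho_2 \cdot
#' \mathrm{Var}(X_2 \mid Y{=}0)} with \eqn{\rho_2 < 1}) around a strongly
#' shifted mean — the "age-like" predictor pattern: the condition at higher
#' values is much more certain. The first predictor is informative
#' (shifted means) but non-separating (comparable spread in both classes).
#'
#' @param n Total sample size (at least 4).
#' @param prop_y0 Proportion of the majority \eqn{Y = 0} class, in (0, 1).
#' @param mean_x1_y0,mean_x1_y1,mean_x2_y0,mean_x2_y1 Class-conditional
#'   means.
#' @param var_x1_y0,var_x2_y0 Class-0 variances (positive). Defaults 9 and
#'   100: on that scale \eqn{X_2 \mid Y{=}1} is markedly more homogeneous
#'   and \eqn{X_2} stays positive.
#' @param var_ratio_x1,var_ratio_x2 Variance ratios
#'   \eqn{\mathrm{Var}(X_j \mid 1)/\mathrm{Var}(X_j \mid 0)}.
#' @param x2_positive Redraw negative \eqn{X_2} values (age-like predictor
#'   is all positive)? Default `TRUE`.
#' @param seed Integer seed for [generate_two_class()].
#' @return An object of class `"two_class_spec"`.
#' @export
two_class_spec <- function(n, prop_y0,
                           mean_x1_y0, mean_x1_y1,
                           mean_x2_y0, mean_x2_y1,
                           var_x1_y0 = 9, var_x2_y0 = 100,
                           var_ratio_x1 = 1.6, var_ratio_x2 = 0.3,
                           x2_positive = TRUE, seed = NULL) {
  n <- as.integer(n)
  if (n < 4L) stop("`n` must be at least 4", call. = FALSE)
  if (prop_y0 <= 0 || prop_y0 >= 1) {
    stop("`prop_y0` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (var_x1_y0 <= 0 || var_x2_y0 <= 0 || var_ratio_x1 <= 0 ||
      var_ratio_x2 <= 0) {
    stop("variances and variance ratios must be positive", call. = FALSE)
  }
  n0 <- round(n * prop_y0)
  if (n0 < 2L || n - n0 < 2L) {
    stop("each class must contain at least 2 observations", call. = FALSE)
  }
  structure(list(n = n, prop_y0 = prop_y0,
                 mean_x1_y0 = mean_x1_y0, mean_x1_y1 = mean_x1_y1,
                 mean_x2_y0 = mean_x2_y0, mean_x2_y1 = mean_x2_y1,
                 var_x1_y0 = var_x1_y0, var_x2_y0 = var_x2_y0,
                 var_ratio_x1 = var_ratio_x1, var_ratio_x2 = var_ratio_x2,
                 x2_positive = isTRUE(x2_positive), seed = seed),
            class = "two_class_spec")
}

#' Preset: main-sample design (Dataset I)
#'
#' The motivating two-predictor design used as the main sample: n = 100 with
#' 85% imbalance towards \eqn{Y = 0}; \eqn{X_1} class means 8.7 / -1.5
#' (informative, non-separating, \eqn{E(X_1|0) = -5.8 \cdot E(X_1|1)});
#' \eqn{X_2} class means 32.9 / 76.6 (separating,
#' \eqn{E(X_2|1) = 2.33 \cdot E(X_2|0)},
#' \eqn{\mathrm{Var}(X_2|1) = 0.3 \cdot \mathrm{Var}(X_2|0)}).
#'
#' @param seed Integer seed.
#' @return A [two_class_spec()].
#' @export
preset_dataset_I <- function(seed = NULL) {
  two_class_spec(n = 100L, prop_y0 = 0.85,
                 mean_x1_y0 = 8.7, mean_x1_y1 = -1.5,
                 mean_x2_y0 = 32.9, mean_x2_y1 = 76.6,
                 seed = seed)
}

#' Preset: new-data design (Dataset II)
#'
#' The companion design used as new data for prediction: n = 50 with 80%
#' imbalance; \eqn{X_1} class means 9.6 / 0.1 and \eqn{X_2} class means
#' 35.9 / 65.6 — the same structure as [preset_dataset_I()] with a slightly
#' lower magnitude of separation.
#'
#' @param seed Integer seed.
#' @return A [two_class_spec()].
#' @export
preset_dataset_II <- function(seed = NULL) {
  two_class_spec(n = 50L, prop_y0 = 0.80,
                 mean_x1_y0 = 9.6, mean_x1_y1 = 0.1,
                 mean_x2_y0 = 35.9, mean_x2_y1 = 65.6,
                 seed = seed)
}

#' Generate a two-class dataset from a specification
#'
#' Allocates exactly `round(n * prop_y0)` observations to class 0 (labels
#' are deterministic, not Bernoulli draws, so the printed imbalance holds
#' exactly), draws the predictors from the class-conditional normal
#' distributions of the spec, optionally redraws negative \eqn{X_2} values,
#' and shuffles the rows. Deterministic given `spec$seed`.
#'
#' @param spec A [two_class_spec()].
#' @return List with `X` (n x 2 matrix, columns `x1`, `x2`), `y` (integer
#'   0/1 labels), and the echoed `spec`.
#' @export
generate_two_class <- function(spec) {
  stopifnot(inherits(spec, "two_class_spec"))
  n0 <- round(spec$n * spec$prop_y0)
  n1 <- spec$n - n0
  sd_x1 <- sqrt(spec$var_x1_y0 * c(1, spec$var_ratio_x1))
  sd_x2 <- sqrt(spec$var_x2_y0 * c(1, spec$var_ratio_x2))
  with_seed(spec$seed, {
    x1 <- c(stats::rnorm(n0, spec$mean_x1_y0, sd_x1[1L]),
            stats::rnorm(n1, spec$mean_x1_y1, sd_x1[2L]))
    draw_x2 <- function(n, mean, sd) {
      v <- stats::rnorm(n, mean, sd)
      if (spec$x2_positive) {
        bad <- which(v < 0)
        while (length(bad)) {
          v[bad] <- stats::rnorm(length(bad), mean, sd)
          bad <- bad[v[bad] < 0]
        }
      }
      v
    }
    x2 <- c(draw_x2(n0, spec$mean_x2_y0, sd_x2[1L]),
            draw_x2(n1, spec$mean_x2_y1, sd_x2[2L]))
    y <- c(rep(0L, n0), rep(1L, n1))
    ord <- sample.int(spec$n)
    list(X = cbind(x1 = x1[ord], x2 = x2[ord]), y = y[ord], spec = spec)
  })
}
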