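#' Fuzzification settings
#'
#' Controls how crisp 0/1 responses and numeric predictors are mapped to
#' triangular fuzzy numbers. A binary response \eqn{y} becomes
#' \eqn{(y - m \ell u,\; y,\; y + m r u)} with a fresh
#' \eqn{u \sim \mathrm{Uniform}(I_L, I_U)} per value; `m` is the degree of
#' fuzziness, and `r`, `ell` skew the right and left spreads. Predictors are
#' standardized and either kept crisp (`predictor_mode = "degenerate"`) or
#' given a symmetric spread \eqn{m \cdot u} (`"symmetric"`, the default).
#'
#' With the default limits \eqn{(I_L, I_U) = (0.001, 0.1)} and
#' \eqn{m = r = \ell = 1}, fuzzified responses always stay inside
#' \eqn{[-1, 1]}, the codomain of the response fuzzifier; `clamp` forces
#' that containment for more aggressive settings.
#'
#' @param m Degree of fuzziness, \eqn{\ge 0}. Default 1.
#' @param r,ell Right- and left-spread factors, \eqn{\ge 0}. Default 1
#'   (symmetric).
#' @param I_L,I_U Lower/upper limits of the uniform spread draw,
#'   `I_L < I_U`. Default 0.001 and 0.1.
#' @param predictor_mode `"symmetric"` (fuzzy predictors) or `"degenerate"`
#'   (crisp predictors).
#' @param clamp Clamp fuzzified response supports to \eqn{[-1, 1]}?
#'   Default `FALSE`.
#' @param seed Integer seed making [fuzzify_dataset()] deterministic, or
#'   `NULL` to use the current random stream.
#' @return An object of class `"fuzzification_config"`.
#' @export
fuzzification_config <- function(m = 1, r = 1, ell = 1,
                                 I_L = 0.001, I_U = 0.1,
                                 predictor_mode = c("symmetric", "degenerate"),
                                 clamp = FALSE, seed = NULL) {
  predictor_mode <- match.arg(predictor_mode)
  for (nm in c("m", "r", "ell", "I_L", "I_U")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (m < 0 || r < 0 || ell < 0) {
    stop("`m`, `r` and `ell` must be nonnegative", call. = FALSE)
  }
  if (I_L >= I_U) stop("`I_L` must be strictly below `I_U`", call. = FALSE)
  structure(list(m = m, r = r, ell = ell, I_L = I_L, I_U = I_U,
                 predictor_mode = predictor_mode, clamp = isTRUE(clamp),
                 seed = seed),
            class = "fuzzification_config")
}

#' Fuzzify binary responses
#'
#' Maps each crisp label \eqn{y \in \{0, 1\}} to the TFN
#' \eqn{(y - m\,\ell\,u,\; y,\; y + m\,r\,u)} with an independent
#' \eqn{u \sim \mathrm{Uniform}(I_L, I_U)} drawn per value from the current
#' random stream. The vertex always equals the crisp label.
#'
#' @param y Vector of 0/1 labels.
#' @param cfg A [fuzzification_config()].
#' @return A [tfn] vector of the same length as `y`.
#' @export
fuzzify_response <- function(y, cfg = fuzzification_config()) {
  if (!all(y %in% c(0, 1))) {
    stop("response values must be 0 or 1", call. = FALSE)
  }
  y <- as.double(y)
  u <- stats::runif(length(y), cfg$I_L, cfg$I_U)
  lo <- y - cfg$m * cfg$ell * u
  hi <- y + cfg$m * cfg$r * u
  if (cfg$clamp) {
    lo <- pmax(lo, -1)
    hi <- pmin(hi, 1)
  }
  tfn(lo, y, hi)
}

#' Fuzzify a numeric predictor column
#'
#' In `"degenerate"` mode each value becomes the crisp TFN \eqn{(x, x, x)}.
#' In `"symmetric"` mode each value receives a symmetric spread
#' \eqn{m \cdot s \cdot u}, with `column_scale` \eqn{s} the column's scale
#' (1 for standardized predictors) and an independent
#' \eqn{u \sim \mathrm{Uniform}(I_L, I_U)} per value.
#'
#' @param x Numeric vector (typically an already standardized column).
#' @param column_scale Positive scale of the column on the fuzzified scale.
#' @param cfg A [fuzzification_config()].
#' @return A [tfn] vector.
#' @export
fuzzify_predictor <- function(x, column_scale = 1,
                              cfg = fuzzification_config()) {
  stopifnot_scalar_number(column_scale, "column_scale")
  if (column_scale <= 0) {
    stop("`column_scale` must be positive", call. = FALSE)
  }
  x <- as.double(x)
  if (cfg$predictor_mode == "degenerate" || cfg$m == 0) {
    return(tfn(x, x, x))
  }
  u <- stats::runif(length(x), cfg$I_L, cfg$I_U)
  s <- cfg$m * column_scale * u
  tfn(x - s, x, x + s)
}

#' Build a fuzzy dataset from crisp inputs
#'
#' Standardizes the predictor matrix (zero mean, unit variance per column),
#' fuzzifies predictors and responses according to `cfg`, and packages the
#' result with the original crisp labels. Deterministic given `cfg$seed`.
#' Standardization centers and scales are stored so that new (e.g. test)
#' data can be fuzzified on the same scale via [fuzzify_newdata()].
#'
#' @param X Numeric matrix or data frame of predictors (no missing values).
#' @param y Vector of 0/1 labels containing both classes.
#' @param cfg A [fuzzification_config()].
#' @param standardize Standardize predictor columns first? Default `TRUE`.
#' @return An object of class `"fuzzy_dataset"`: a list with the three
#'   defining-point matrices `X_lower`, `X_vertex`, `X_upper`, the fuzzy
#'   response `Y` (a [tfn]), the crisp labels `y_crisp`, `column_names`,
#'   and the standardization `center`/`scale`.
#' @export
fuzzify_dataset <- function(X, y, cfg = fuzzification_config(),
                            standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L || ncol(X) == 0L) {
    stop("`X` must have at least one row and one column", call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("`y` must have one label per row of `X`", call. = FALSE)
  }
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) {
    stop(sprintf("missing value in `X` at row %d, column %d",
                 na_idx[1L, 1L], na_idx[1L, 2L]), call. = FALSE)
  }
  if (anyNA(y)) {
    stop(sprintf("missing value in `y` at position %d", which(is.na(y))[1L]),
         call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("response values must be 0 or 1", call. = FALSE)
  }
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
    degenerate <- !is.finite(scale_) | scale_ == 0
    scale_[degenerate] <- 1  # constant columns pass through centered only
    Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scale_, "/")
  } else {
    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
    Xs <- X
  }
  with_seed(cfg$seed, {
    Y <- fuzzify_response(y, cfg)
    X_lower <- X_upper <- Xs
    if (cfg$predictor_mode == "symmetric" && cfg$m > 0) {
      for (j in seq_len(ncol(Xs))) {
        col <- fuzzify_predictor(Xs[, j], 1, cfg)
        X_lower[, j] <- unclass(col)[, 1L]
        X_upper[, j] <- unclass(col)[, 3L]
      }
    }
    structure(list(X_lower = X_lower, X_vertex = Xs, X_upper = X_upper,
                   Y = Y, y_crisp = as.integer(y), column_names = nms,
                   center = center, scale = scale_, config = cfg),
              class = "fuzzy_dataset")
  })
}

#' Fuzzify new predictor data on an existing dataset's scale
#'
#' Applies the standardization (center/scale) recorded in a fitted
#' [fuzzy_dataset()] to new crisp predictors and fuzzifies them with the same
#' configuration — the test-data counterpart of [fuzzify_dataset()].
#'
#' @param data A `"fuzzy_dataset"` (provides center, scale and config).
#' @param X New numeric predictor matrix with the same columns.
#' @param seed Optional seed for the new spread draws.
#' @return A `"fuzzy_dataset"` without a response (`Y` and `y_crisp` are
#'   `NULL` unless supplied downstream).
#' @export
fuzzify_newdata <- function(data, X, seed = NULL) {
  stopifnot(inherits(data, "fuzzy_dataset"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(data$center)) {
    stop("new data must have the same predictor columns as the training set",
         call. = FALSE)
  }
  cfg <- data$config
  Xs <- sweep(sweep(X, 2L, data$center, "-"), 2L, data$scale, "/")
  with_seed(seed, {
    X_lower <- X_upper <- Xs
    if (cfg$predictor_mode == "symmetric" && cfg$m > 0) {
      for (j in seq_len(ncol(Xs))) {
        col <- fuzzify_predictor(Xs[, j], 1, cfg)
        X_lower[, j] <- unclass(col)[, 1L]
        X_upper[, j] <- unclass(col)[, 3L]
      }
    }
    structure(list(X_lower = X_lower, X_vertex = Xs, X_upper = X_upper,
                   Y = NULL, y_crisp = NULL, column_names = data$column_names,
                   center = data$center, scale = data$scale, config = cfg),
              class = "fuzzy_dataset")
  })
}

#' @export
print.fuzzy_dataset <- function(x, ...) {
  cat(sprintf("<fuzzy_dataset> %d observations, %d predictors (%s)\n",
              nrow(x$X_vertex), ncol(x$X_vertex),
              paste(x$column_names, collapse = ", ")))
  if (!is.null(x$y_crisp)) {
    tab <- table(x$y_crisp)
    cat(sprintf("  classes: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  cat(sprintf("  fuzziness m = %g, predictor mode = %s\n",
              x$config$m, x$config$predictor_mode))
  invisible(x)
}

# Extract column j of the fuzzy predictor block as a tfn vector.
fuzzy_column <- function(data, j) {
  tfn(data$X_lower[, j], data$X_vertex[, j], data$X_upper[, j])
}
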