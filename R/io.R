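#' Read a delimited classification dataset
#'
#' Reads a comma-delimited text table with a header row, validates that all
#' predictor columns are numeric and the response column is 0/1, and splits
#' it into a predictor matrix and label vector. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param response Name of the 0/1 response column.
#' @return List with `X` (numeric matrix), `y` (integer labels), and
#'   `names` (predictor column names).
#' @export
read_dataset <- function(path, response) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!response %in% names(df)) {
    stop(sprintf("response column '%s' not found; available columns: %s",
                 response, paste(names(df), collapse = ", ")), call. = FALSE)
  }
  y_raw <- df[[response]]
  if (!is.numeric(y_raw) || !all(y_raw %in% c(0, 1))) {
    bad <- which(!(y_raw %in% c(0, 1)))[1L]
    stop(sprintf("response column '%s' must be 0/1; offending value '%s' at row %d",
                 response, as.character(y_raw[bad]), bad), call. = FALSE)
  }
  pred <- df[setdiff(names(df), response)]
  for (nm in names(pred)) {
    if (!is.numeric(pred[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(pred[[nm]])))))[1L]
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   as.character(pred[[nm]][bad]), nm,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  list(X = as.matrix(pred), y = as.integer(y_raw), names = names(pred))
}

#' Save and load fitted fuzzy logistic regression models
#'
#' Models are persisted as JSON: coefficient triples, the chosen
#' optimization measure, the search configuration, fuzzification settings,
#' and the training standardization. Serialization is deterministic, so two
#' runs with identical seeds produce byte-identical files.
#'
#' @param fit A fitted [flr()] model.
#' @param path Output / input file path.
#' @return `write_flr_json` returns `path` invisibly; `read_flr_json`
#'   returns an object of class `"flr"`.
#' @export
write_flr_json <- function(fit, path) {
  stopifnot(inherits(fit, "flr"))
  cm <- unclass(fit$coefficients)
  doc <- list(
    model = "fuzzy_logistic_regression",
    coefficients = lapply(seq_len(nrow(cm)), function(i) {
      list(term = c("(Intercept)", fit$column_names)[i],
           a1 = cm[i, 1L], a2 = cm[i, 2L], a3 = cm[i, 3L])
    }),
    chosen_measure = fit$chosen_measure,
    measure_variations = as.list(fit$measure_variations),
    best_error = fit$best_error,
    column_names = fit$column_names,
    center = fit$center, scale = fit$scale,
    fuzzification = fit$fuzzification[c("m", "r", "ell", "I_L", "I_U",
                                        "predictor_mode", "clamp", "seed")],
    search = fit$config[c("I_minus", "I_plus", "n_candidates",
                          "n_repetitions", "error_kind", "error_points",
                          "seed")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_flr_json
#' @export
read_flr_json <- function(path) {
  doc <- jsonlite::read_json(path)
  cm <- do.call(rbind, lapply(doc$coefficients, function(co) {
    c(co$a1, co$a2, co$a3)
  }))
  fuzz <- doc$fuzzification
  fc <- fuzzification_config(m = fuzz$m, r = fuzz$r, ell = fuzz$ell,
                             I_L = fuzz$I_L, I_U = fuzz$I_U,
                             predictor_mode = fuzz$predictor_mode,
                             clamp = isTRUE(fuzz$clamp),
                             seed = fuzz$seed)
  sc <- flr_search_config(I_minus = doc$search$I_minus,
                          I_plus = doc$search$I_plus,
                          n_candidates = doc$search$n_candidates,
                          n_repetitions = doc$search$n_repetitions,
                          error_kind = doc$search$error_kind,
                          error_points = doc$search$error_points,
                          seed = doc$search$seed)
  structure(list(coefficients = tfn(cm[, 1L], cm[, 2L], cm[, 3L]),
                 chosen_measure = doc$chosen_measure,
                 measure_variations = unlist(doc$measure_variations),
                 best_error = doc$best_error,
                 best_errors = NULL, search_log = NULL,
                 column_names = unlist(doc$column_names),
                 center = unlist(doc$center), scale = unlist(doc$scale),
                 fuzzification = fc, config = sc),
            class = "flr")
}

#' Published benchmark fixtures
#'
#' Accessors for the small plain-text tables shipped with the package:
#' `published_confusion_matrices()` returns the three motivating-example
#' confusion matrices (main-sample model with one predictor, with both
#' predictors, and the two-predictor model applied to new data);
#' `published_coefficients()` the largest reported TFN coefficient per
#' clinical dataset; `published_scores()` the reported per-dataset
#' cross-validation scores for the fuzzy logistic regression (with and
#' without SMOTE) and the SMOTE-KNN sensitivity column.
#'
#' @return Data frames read from `inst/extdata/`.
#' @export
published_confusion_matrices <- function() {
  utils::read.csv(system.file("extdata", "published_confusion.csv",
                              package = "fuzzylogit"))
}

#' @rdname published_confusion_matrices
#' @export
published_coefficients <- function() {
  utils::read.csv(system.file("extdata", "published_coefficients.csv",
                              package = "fuzzylogit"))
}

#' @rdname published_confusion_matrices
#' @export
published_scores <- function() {
  utils::read.csv(system.file("extdata", "published_scores.csv",
                              package = "fuzzylogit"))
}
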