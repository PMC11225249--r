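#' Run configuration
#'
#' Bundles the nested module configurations behind one master seed: the
#' fuzzification, coefficient-search, SMOTE and split streams are all
#' derived deterministically from `seed`, so a pipeline run is reproducible
#' end to end. Values can be overridden individually or loaded from a flat
#' `key = value` config file via [read_run_config()].
#'
#' @param seed Master integer seed (default 1).
#' @param fuzzification A [fuzzification_config()].
#' @param search A [flr_search_config()].
#' @param threshold A [fuzzy_threshold()].
#' @param n_splits,train_fraction,smote Cross-validation settings.
#' @param sep_max_iter,sep_tol,sep_threshold Separation-diagnostic settings.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       fuzzification = fuzzification_config(),
                       search = flr_search_config(),
                       threshold = fuzzy_threshold(),
                       n_splits = 10L, train_fraction = 0.7, smote = FALSE,
                       sep_max_iter = 100L, sep_tol = 1e-8,
                       sep_threshold = 10) {
  fuzzification$seed <- derive_seed(seed, 11L)
  search$seed <- derive_seed(seed, 23L)
  structure(list(seed = as.integer(seed), fuzzification = fuzzification,
                 search = search, threshold = threshold,
                 n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, smote = isTRUE(smote),
                 sep_max_iter = as.integer(sep_max_iter), sep_tol = sep_tol,
                 sep_threshold = sep_threshold),
            class = "run_config")
}

#' Read a flat key = value configuration file
#'
#' Parses lines of the form `key = value` (or `key: value`; `#` comments
#' and blank lines ignored) and builds a [run_config()]. Recognized keys:
#' `seed`, `m`, `r`, `ell`, `I_L`, `I_U`, `predictor_mode`, `I_minus`,
#' `I_plus`, `n_candidates`, `n_repetitions`, `tau1`, `tau2`, `tau3`,
#' `n_splits`, `train_fraction`, `smote`, `sep_max_iter`, `sep_tol`,
#' `sep_threshold`.
#'
#' @param path Path to the config file.
#' @param overrides Named list applied on top of file values (CLI flags
#'   override the file).
#' @return A [run_config()].
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    }
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", ln))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("cannot parse config line: '%s'", ln), call. = FALSE)
      }
      vals[[m[2L]]] <- m[3L]
    }
  }
  vals[names(overrides)] <- overrides
  num <- function(key, default) {
    if (is.null(vals[[key]])) default else as.numeric(vals[[key]])
  }
  chr <- function(key, default) {
    if (is.null(vals[[key]])) default else as.character(vals[[key]])
  }
  lgl <- function(key, default) {
    if (is.null(vals[[key]])) default
    else tolower(as.character(vals[[key]])) %in% c("true", "1", "yes")
  }
  run_config(
    seed = num("seed", 1),
    fuzzification = fuzzification_config(
      m = num("m", 1), r = num("r", 1), ell = num("ell", 1),
      I_L = num("I_L", 0.001), I_U = num("I_U", 0.1),
      predictor_mode = chr("predictor_mode", "symmetric")),
    search = flr_search_config(
      I_minus = num("I_minus", -2), I_plus = num("I_plus", 2),
      n_candidates = num("n_candidates", 500),
      n_repetitions = num("n_repetitions", 20)),
    threshold = fuzzy_threshold(num("tau1", 0.4), num("tau2", 0.5),
                                num("tau3", 0.6)),
    n_splits = num("n_splits", 10), train_fraction = num("train_fraction", 0.7),
    smote = lgl("smote", FALSE),
    sep_max_iter = num("sep_max_iter", 100), sep_tol = num("sep_tol", 1e-8),
    sep_threshold = num("sep_threshold", 10))
}

#' Run a pipeline command
#'
#' Dispatches the tool's commands and writes their artifacts to `out_dir`.
#' Commands:
#' \describe{
#'   \item{`simulate`}{Generate a synthetic two-class dataset (`preset`
#'     `"I"` or `"II"`) and write `dataset.csv` plus a JSON spec sidecar.}
#'   \item{`fit`}{Fuzzify `input` and fit the fuzzy logistic regression;
#'     writes `model.json`.}
#'   \item{`predict`}{Apply `model` (a model.json) to `input`; writes
#'     `predictions.csv` with the prediction TFN, fuzzy probability,
#'     expected probability and crisp label per row.}
#'   \item{`diagnose-separation`}{IRLS trajectory + separation verdict;
#'     writes `separation.json` and `trajectory.csv`.}
#'   \item{`evaluate`}{Repeated stratified split cross-validation of the
#'     fuzzy model on `input`; writes `cv_metrics.json` and
#'     `cv_splits.csv`.}
#'   \item{`benchmark`}{Fuzzy vs classical logistic baseline over two
#'     simulated preset datasets (or `input` plus a simulated one);
#'     writes `benchmark.json`.}
#' }
#'
#' @param command One of the commands above.
#' @param input Path to a CSV dataset (where required).
#' @param response Response column name (default `"y"`).
#' @param model Path to a model JSON (for `predict`).
#' @param preset Synthetic preset `"I"` or `"II"` (for `simulate`).
#' @param out_dir Output directory (created if missing).
#' @param cfg A [run_config()].
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "predict",
                                     "diagnose-separation", "evaluate",
                                     "benchmark"),
                         input = NULL, response = "y", model = NULL,
                         preset = "I", out_dir = ".",
                         cfg = run_config()) {
  command <- match.arg(command)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir),
                  call. = FALSE)
  }
  need_input <- function() {
    if (is.null(input)) {
      stop(sprintf("command '%s' requires --input", command), call. = FALSE)
    }
    read_dataset(input, response)
  }
  written <- character()
  emit <- function(path) written <<- c(written, path)

  if (command == "simulate") {
    spec <- switch(preset,
                   I = preset_dataset_I(seed = cfg$seed),
                   II = preset_dataset_II(seed = cfg$seed),
                   stop("`preset` must be 'I' or 'II'", call. = FALSE))
    d <- generate_two_class(spec)
    ds_path <- file.path(out_dir, "dataset.csv")
    utils::write.csv(data.frame(x1 = d$X[, 1L], x2 = d$X[, 2L], y = d$y),
                     ds_path, row.names = FALSE)
    emit(ds_path)
    spec_path <- file.path(out_dir, "dataset_spec.json")
    jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    emit(spec_path)
  } else if (command == "fit") {
    ds <- need_input()
    fd <- fuzzify_dataset(ds$X, ds$y, cfg$fuzzification)
    fit <- flr(fd, cfg$search)
    mp <- file.path(out_dir, "model.json")
    write_flr_json(fit, mp)
    emit(mp)
  } else if (command == "predict") {
    if (is.null(model)) stop("command 'predict' requires --model", call. = FALSE)
    fit <- read_flr_json(model)
    ds <- need_input_or_matrix(input, response, fit)
    pred <- predict(fit, ds$X, tau = cfg$threshold,
                    seed = derive_seed(cfg$seed, 31L))
    pp <- file.path(out_dir, "predictions.csv")
    utils::write.csv(as.data.frame(pred), pp, row.names = FALSE)
    emit(pp)
  } else if (command == "diagnose-separation") {
    ds <- need_input()
    traj <- irls_fit(ds$X, ds$y, max_iter = cfg$sep_max_iter,
                     tol = cfg$sep_tol)
    rep_ <- detect_separation(traj, threshold = cfg$sep_threshold)
    sp <- file.path(out_dir, "separation.json")
    jsonlite::write_json(list(verdict = rep_$verdict,
                              converged = traj$converged,
                              n_iter = traj$n_iter,
                              threshold = rep_$threshold_used,
                              flagged = rep_$flagged_predictors),
                         sp, auto_unbox = TRUE, digits = NA, null = "null")
    emit(sp)
    tp <- file.path(out_dir, "trajectory.csv")
    utils::write.csv(data.frame(iteration = seq_len(traj$n_iter),
                                traj$estimates, check.names = FALSE),
                     tp, row.names = FALSE)
    emit(tp)
  } else if (command == "evaluate") {
    ds <- need_input()
    model_c <- flr_classifier(cfg$fuzzification, cfg$search, cfg$threshold,
                              seed = derive_seed(cfg$seed, 41L))
    cv <- repeated_split_cv(model_c, ds$X, ds$y, n_splits = cfg$n_splits,
                            train_fraction = cfg$train_fraction,
                            smote = cfg$smote,
                            seed = derive_seed(cfg$seed, 43L))
    mj <- file.path(out_dir, "cv_metrics.json")
    jsonlite::write_json(c(list(n_splits = cv$n_splits,
                                train_fraction = cv$train_fraction,
                                smote = cv$smote, seed = cfg$seed),
                           unclass(cv$mean_metrics)),
                         mj, auto_unbox = TRUE, digits = NA, null = "null")
    emit(mj)
    sc <- file.path(out_dir, "cv_splits.csv")
    utils::write.csv(cv$per_split, sc, row.names = FALSE)
    emit(sc)
  } else if (command == "benchmark") {
    datasets <- list()
    if (!is.null(input)) {
      ds <- need_input()
      datasets$input <- list(X = ds$X, y = ds$y)
    }
    d1 <- generate_two_class(preset_dataset_I(seed = derive_seed(cfg$seed, 51L)))
    d2 <- generate_two_class(preset_dataset_II(seed = derive_seed(cfg$seed, 53L)))
    datasets$dataset_I <- list(X = d1$X, y = d1$y)
    datasets$dataset_II <- list(X = d2$X, y = d2$y)
    models <- list(
      FLR = flr_classifier(cfg$fuzzification, cfg$search, cfg$threshold,
                           seed = derive_seed(cfg$seed, 61L)),
      CLR = clr_classifier(max_iter = cfg$sep_max_iter, tol = cfg$sep_tol))
    rc <- benchmark_models(models, datasets, metric = "f1",
                           n_splits = cfg$n_splits,
                           train_fraction = cfg$train_fraction,
                           smote = cfg$smote, seed = derive_seed(cfg$seed, 67L))
    bj <- file.path(out_dir, "benchmark.json")
    jsonlite::write_json(list(metric = "f1",
                              score_table = as.data.frame(rc$score_table),
                              avg_ranks = as.list(rc$avg_ranks),
                              Q = rc$Q, F_f = rc$F_f, p_value = rc$p_value,
                              CD = rc$CD),
                         bj, auto_unbox = TRUE, digits = NA, null = "null")
    emit(bj)
  }
  invisible(written)
}

# For `predict`: the input table may or may not carry a response column.
need_input_or_matrix <- function(input, response, fit) {
  if (is.null(input)) stop("command 'predict' requires --input", call. = FALSE)
  df <- utils::read.csv(input, check.names = FALSE)
  if (response %in% names(df)) {
    ds <- read_dataset(input, response)
    if (all(fit$column_names %in% colnames(ds$X))) {
      ds$X <- ds$X[, fit$column_names, drop = FALSE]
    }
    list(X = ds$X, y = ds$y)
  } else {
    keep <- intersect(fit$column_names, names(df))
    if (length(keep) != length(fit$column_names)) {
      stop(sprintf("input is missing model columns: %s",
                   paste(setdiff(fit$column_names, names(df)),
                         collapse = ", ")), call. = FALSE)
    }
    list(X = as.matrix(df[fit$column_names]), y = NULL)
  }
}
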