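## Orchestration and I/O: CSV round-trips, run configuration, and the
## end-to-end synthetic study runner.

#' Load a crash dataset from CSV
#'
#' Expects one header row, a 0/1 outcome column (`fatal` by default) and one
#' column per factor holding level labels.  Factor columns are
#' dummy-expanded against the declared reference levels and a constant
#' column is prepended; row order is preserved.
#'
#' @param path CSV file path.
#' @param factors List of [factor_spec()]s declaring columns, levels and
#'   reference levels (default: the census emulation factors).
#' @param outcome Name of the outcome column.
#' @return A [crash_dataset()].
#' @export
load_dataset <- function(path, factors = florida_factor_specs(),
                         outcome = "fatal") {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!outcome %in% names(df)) {
    stop("outcome column `", outcome, "` not found in ", path)
  }
  yraw <- df[[outcome]]
  bad <- which(!yraw %in% c("0", "1"))
  if (length(bad)) {
    stop("outcome column `", outcome, "` must be 0/1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  fac_names <- vapply(factors, `[[`, character(1), "name")
  missing <- setdiff(fac_names, names(df))
  if (length(missing)) {
    stop("dataset is missing factor column(s): ",
         paste(missing, collapse = ", "))
  }
  frame <- df[fac_names]
  X <- build_design(frame, factors)
  crash_dataset(as.integer(yraw), X, frame = frame, factors = factors)
}

#' Write a crash dataset to CSV
#'
#' Writes the outcome column (named `fatal`) followed by one column of
#' level labels per factor; [load_dataset()] on the result is an identity
#' round-trip.
#'
#' @param data A [crash_dataset()] carrying its raw `frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "crash_dataset"))
  if (is.null(data$frame)) {
    stop("dataset has no raw factor frame; cannot serialise to CSV")
  }
  out <- cbind(data.frame(fatal = data$y), data$frame)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Configuration of an end-to-end study run
#'
#' Exactly one data source must be given: a [generator_spec()] (synthetic
#' population) or a CSV path.
#'
#' @param spec Optional [generator_spec()].
#' @param data_path Optional CSV path readable by [load_dataset()].
#' @param factors Factor declarations used when loading from CSV.
#' @param ratio Event ratio of the choice-based subsample.
#' @param method Correction method used for the headline RELM arm.
#' @param threshold Classification threshold.
#' @param tau Optional population event fraction override; by default
#'   \eqn{\tau} is computed from the supplied population, but when fitting a
#'   pre-subsampled file the prior must be supplied by the user.
#' @param sweep_grid Optional event-ratio grid; `NULL` skips the sweep.
#' @param cv_k Optional fold count; `NULL` skips cross-validation.
#' @param bias_correct Apply the coefficient bias correction.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Optional output directory for the JSON report and CSV
#'   intermediates.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = NULL, data_path = NULL,
                       factors = florida_factor_specs(),
                       ratio = 0.43, method = c("weighting", "prior"),
                       threshold = 0.5, tau = NULL,
                       sweep_grid = NULL, cv_k = NULL,
                       bias_correct = TRUE, seed = 1L, out_dir = NULL) {
  if (is.null(spec) == is.null(data_path)) {
    stop("give exactly one data source: `spec` or `data_path`")
  }
  if (!is.null(spec)) stopifnot(inherits(spec, "generator_spec"))
  method <- match.arg(method)
  assert_fraction(ratio, "ratio")
  assert_fraction(threshold, "threshold", open = FALSE)
  if (!is.null(tau)) assert_fraction(tau, "tau")
  structure(list(spec = spec, data_path = data_path, factors = factors,
                 ratio = ratio, method = method, threshold = threshold,
                 tau = tau, sweep_grid = sweep_grid, cv_k = cv_k,
                 bias_correct = bias_correct, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

coef_table <- function(beta, cov) {
  se <- sqrt(pmax(diag(cov), 0))
  data.frame(term = names(beta), estimate = unname(beta), se = se,
             lower = unname(beta) - 1.96 * se,
             upper = unname(beta) + 1.96 * se,
             row.names = NULL)
}

#' Run the full study design end to end
#'
#' Generates (or loads) the population, fits the plain logistic model on
#' the full data, draws the choice-based subsample, fits the naive,
#' prior-corrected and weighting-corrected models on it, predicts on the
#' full population, and summarises classification counts at the threshold
#' plus AUCs.  Optionally runs the event-ratio sweep and the stratified
#' K-fold cross-validation.  Fully deterministic given the master seed.
#'
#' Classification mirrors the published evaluation design: the plain
#' logistic model is thresholded on its own fitted probabilities, while the
#' rare-events arms are thresholded on sample-scale corrected probabilities
#' (see [corrected_probability()]).
#'
#' @param config A [run_config()].
#' @return An object of class `run_report` (a list): configuration echo,
#'   sampling bookkeeping, coefficient tables with 95% confidence
#'   intervals, confusion summaries, AUCs, and any sweep / CV results.  If
#'   `config$out_dir` is set, `report.json`, `sample.csv` and (when run)
#'   `sweep.csv` are written there.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  data <- if (!is.null(config$spec)) {
    generate_population(config$spec, seed = derive_seed(seed, 1))
  } else {
    load_dataset(config$data_path, factors = config$factors)
  }

  ## plain logistic model on the full population
  red <- drop_unidentifiable(data)
  lm_fit <- fit_logit(red$data)
  lm_scores <- plogis(drop(data$X[, red$kept, drop = FALSE] %*% lm_fit$beta))

  ## choice-based subsample and corrected fits
  ss <- case_based_subsample(data, config$ratio, seed = derive_seed(seed, 2))
  info <- if (is.null(config$tau)) ss$info else {
    sample_info(config$tau, ss$info$ybar)
  }
  red_s <- drop_unidentifiable(ss$sample, screen_separation = TRUE)
  naive_fit <- fit_logit(red_s$data)
  prior_rf <- expand_relm_fit(
    correct_fit(naive_fit, red_s$data, info, method = "prior",
                bias_correct = config$bias_correct),
    data$column_names, red_s$kept)
  weight_rf <- expand_relm_fit(
    correct_fit(fit_weighted_logit(red_s$data, info), red_s$data, info,
                method = "weighting", bias_correct = config$bias_correct),
    data$column_names, red_s$kept)
  relm_rf <- if (config$method == "prior") prior_rf else weight_rf

  relm_cls <- corrected_probability(relm_rf, data, scale = "sample")$p
  relm_pop <- corrected_probability(relm_rf, data, scale = "population")$p

  cm_lm <- confusion(classify(lm_scores, config$threshold), data$y)
  cm_relm <- confusion(classify(relm_cls, config$threshold), data$y)

  report <- list(
    config = list(ratio = config$ratio, method = config$method,
                  threshold = config$threshold, seed = seed,
                  bias_correct = config$bias_correct,
                  source = if (is.null(config$spec)) config$data_path
                           else "generator_spec"),
    n = data$n, n_events = sum(data$y),
    sample = list(n = ss$sample$n, n_events = sum(ss$sample$y),
                  tau = info$tau, ybar = info$ybar,
                  omega1 = info$omega1, omega0 = info$omega0,
                  prior_offset = prior_offset(info)),
    coefficients = list(
      lm = coef_table(lm_fit$beta, lm_fit$cov),
      naive = coef_table(naive_fit$beta, naive_fit$cov),
      prior = coef_table(prior_rf$beta_tilde, prior_rf$cov_tilde),
      weighting = coef_table(weight_rf$beta_tilde, weight_rf$cov_tilde)
    ),
    convergence = list(lm = lm_fit$iterations, naive = naive_fit$iterations),
    confusion = list(lm = unclass(cm_lm), relm = unclass(cm_relm)),
    auc = list(lm = roc_curve(lm_scores, data$y)$auc,
               relm = roc_curve(relm_pop, data$y)$auc),
    version = as.character(utils::packageVersion("crashrelm"))
  )

  if (!is.null(config$sweep_grid)) {
    report$sweep <- ratio_sweep(data, grid = config$sweep_grid,
                                threshold = config$threshold,
                                seed = derive_seed(seed, 3),
                                bias_correct = config$bias_correct)
  }
  if (!is.null(config$cv_k)) {
    report$cv <- list(
      relm = kfold_auc(data, K = config$cv_k, seed = derive_seed(seed, 4),
                       model = "relm", ratio = config$ratio,
                       method = config$method,
                       bias_correct = config$bias_correct),
      lm = kfold_auc(data, K = config$cv_k, seed = derive_seed(seed, 4),
                     model = "lm")
    )
  }
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass_report(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_dataset(ss$sample, file.path(config$out_dir, "sample.csv"))
    if (!is.null(report$sweep)) {
      write.csv(report$sweep, file.path(config$out_dir, "sweep.csv"),
                row.names = FALSE)
    }
  }
  report
}

unclass_report <- function(report) {
  report <- unclass(report)
  if (!is.null(report$sweep)) report$sweep <- as.data.frame(report$sweep)
  if (!is.null(report$cv)) {
    report$cv <- lapply(report$cv, function(cv) cv[c("mean_auc", "fold_auc")])
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  population: %d records, %d events (%.4f%%)\n",
              x$n, x$n_events, 100 * x$n_events / x$n))
  cat(sprintf("  sample: %d records, ybar=%.4f, tau=%.6f, offset=%.4f\n",
              x$sample$n, x$sample$ybar, x$sample$tau,
              x$sample$prior_offset))
  cat(sprintf("  LM:   flagged %d, ACR %.1f%%, FCR %.1f%%, AUC %.4f\n",
              x$confusion$lm$n_predicted_events, 100 * x$confusion$lm$acr,
              100 * x$confusion$lm$fcr, x$auc$lm))
  cat(sprintf("  RELM (%s): flagged %d, ACR %.1f%%, FCR %.1f%%, AUC %.4f\n",
              x$config$method, x$confusion$relm$n_predicted_events,
              100 * x$confusion$relm$acr, 100 * x$confusion$relm$fcr,
              x$auc$relm))
  if (!is.null(x$cv)) {
    cat(sprintf("  5-fold CV AUC: RELM %.4f, LM %.4f\n",
                x$cv$relm$mean_auc, x$cv$lm$mean_auc))
  }
  invisible(x)
}
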