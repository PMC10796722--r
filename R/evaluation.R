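## Evaluation harness: threshold classification, ACR/FCR, ROC curve with
## trapezoidal AUC, stratified K-fold cross-validation, and the event-ratio
## sweep.

#' Threshold classification
#'
#' Labels record `i` as an event iff `p[i] > threshold` (strict), so a
#' threshold of 1 labels nothing and a threshold of 0 labels every record
#' with positive score.
#'
#' @param p Numeric score/probability vector.
#' @param threshold Classification threshold in \[0, 1\].
#' @return Integer 0/1 vector.
#' @export
classify <- function(p, threshold) {
  assert_fraction(threshold, "threshold", open = FALSE)
  stopifnot(is.numeric(p))
  as.integer(p > threshold)
}

#' Classification counts and rates
#'
#' Summarises predicted labels against the truth.  The accurate
#' classification rate (ACR) is the fraction of actual events that were
#' flagged (sensitivity at the threshold); the false classification rate
#' (FCR) is the fraction of actual non-events that were falsely flagged.
#'
#' @param labels Predicted 0/1 labels.
#' @param truth Actual 0/1 outcomes; both classes must be present.
#' @return An object of class `confusion_summary` with fields `n_total`,
#'   `n_events`, `n_predicted_events`, `true_positives`, `false_positives`,
#'   `acr`, `fcr`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(labels, truth) {
  labels <- as.integer(labels)
  truth <- as.integer(truth)
  if (length(labels) != length(truth)) stop("labels and truth differ in length")
  if (!all(labels %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("labels and truth must be 0/1")
  }
  n_events <- sum(truth == 1L)
  n_nonevents <- sum(truth == 0L)
  if (n_events == 0L || n_nonevents == 0L) {
    stop("truth must contain at least one event and one non-event")
  }
  tp <- sum(labels == 1L & truth == 1L)
  fp <- sum(labels == 1L & truth == 0L)
  structure(list(n_total = length(truth), n_events = n_events,
                 n_predicted_events = sum(labels == 1L),
                 true_positives = tp, false_positives = fp,
                 acr = tp / n_events, fcr = fp / n_nonevents),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(paste0("<confusion_summary> n=%d, events=%d, flagged=%d, ",
                     "TP=%d, FP=%d, ACR=%.1f%%, FCR=%.1f%%\n"),
              x$n_total, x$n_events, x$n_predicted_events,
              x$true_positives, x$false_positives,
              100 * x$acr, 100 * x$fcr))
  invisible(x)
}

#' ROC curve with trapezoidal AUC
#'
#' Sweeps the threshold over every distinct score, grouping tied scores
#' into a single step (so blocks of ties appear as diagonal segments), and
#' integrates the curve by the trapezoidal rule.  The resulting AUC equals
#' the Mann-Whitney concordance probability: the chance that a random event
#' outscores a random non-event, ties counted one half.
#'
#' @param p Numeric score vector.
#' @param truth Actual 0/1 outcomes; both classes must be present.
#' @return An object of class `roc_result` with fields `thresholds`
#'   (descending, starting at `Inf`), `tpr`, `fpr` (both starting at 0 and
#'   ending at 1) and `auc`.
#' @export
roc_curve <- function(p, truth) {
  truth <- as.integer(truth)
  if (length(p) != length(truth)) stop("p and truth differ in length")
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("truth must contain at least one event and one non-event")
  }
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  ys <- truth[ord]
  last_of_tie <- c(ps[-1L] != ps[-length(ps)], TRUE)
  tp <- cumsum(ys)[last_of_tie]
  fp <- cumsum(1L - ys)[last_of_tie]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, ps[last_of_tie]),
                 tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

## Stratified fold assignment: within each class, shuffled indices receive
## fold ids 1..K cyclically, so per-class fold counts differ by at most 1.
stratified_folds <- function(y, K, seed) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(1L, 0L)) {
    idx <- which(y == cls)
    if (length(idx) < K) {
      stop("class ", cls, " has ", length(idx),
           " records, fewer than K = ", K)
    }
    fold[sample(idx)] <- rep_len(seq_len(K), length(idx))
  }
  fold
}

## Drop design columns that are not identifiable on this (sub)sample:
## all-zero dummies and collinear columns (found by pivoted QR), and —
## when `screen_separation` — dummies that perfectly predict the outcome
## among their active rows, which would send the MLE to infinity.  Mirrors
## what standard logit software does when a level is absent from, or pure
## in, a small case-control sample.
drop_unidentifiable <- function(data, screen_separation = FALSE) {
  p <- ncol(data$X)
  keep_mask <- rep(TRUE, p)
  if (screen_separation && p > 1L) {
    for (j in 2:p) {
      yj <- data$y[data$X[, j] == 1]
      if (length(yj) > 0L && (all(yj == 1L) || all(yj == 0L))) {
        keep_mask[j] <- FALSE
      }
    }
  }
  Xk <- data$X[, keep_mask, drop = FALSE]
  qrx <- qr(Xk)
  kept <- sort(which(keep_mask)[qrx$pivot[seq_len(qrx$rank)]])
  if (!1L %in% kept) stop("intercept column lost in rank reduction")
  if (length(kept) == p) {
    return(list(data = data, kept = seq_len(p), dropped = character()))
  }
  reduced <- crash_dataset(data$y, data$X[, kept, drop = FALSE],
                           frame = data$frame, factors = data$factors,
                           truth = data$truth)
  list(data = reduced, kept = kept,
       dropped = colnames(data$X)[-kept])
}

## Expand a relm_fit obtained on reduced columns back to the full column
## set, with zero coefficients (reference-level risk) for dropped dummies.
expand_relm_fit <- function(rf, column_names, kept) {
  p <- length(column_names)
  beta <- setNames(numeric(p), column_names)
  beta[kept] <- rf$beta_tilde
  cov <- matrix(0, p, p, dimnames = list(column_names, column_names))
  cov[kept, kept] <- rf$cov_tilde
  base_beta <- setNames(numeric(p), column_names)
  base_beta[kept] <- rf$base$beta
  rf$beta_tilde <- beta
  rf$cov_tilde <- cov
  rf$base$beta <- base_beta
  rf$kept <- kept
  rf
}

## One subsample -> corrected fit, dropping unidentifiable columns and
## restoring full coordinates.  Shared by the sweep, the CV loop and
## run_study().
fit_relm_pipeline <- function(sample, info, method, bias_correct = TRUE,
                              column_names = sample$column_names) {
  red <- drop_unidentifiable(sample, screen_separation = TRUE)
  fit <- if (method == "weighting") {
    fit_weighted_logit(red$data, info)
  } else {
    fit_logit(red$data)
  }
  rf <- correct_fit(fit, red$data, info, method = method,
                    bias_correct = bias_correct)
  expand_relm_fit(rf, column_names, red$kept)
}

#' Stratified K-fold cross-validated AUC
#'
#' Partitions the data into K stratified folds (per-class fold sizes differ
#' by at most one record, so every fold contains events even at sub-percent
#' prevalence), trains the configured model on K-1 folds and scores the
#' held-out fold, and reports the per-fold and mean validation AUCs.  For
#' `model = "relm"` the full pipeline runs inside each training portion:
#' choice-based subsampling at `ratio` (with \eqn{\tau} computed from the
#' training portion), corrected fit, corrected probabilities.  For
#' `model = "lm"` a plain logistic fit on the whole training portion is
#' used.
#'
#' @param data A [crash_dataset()].
#' @param K Number of folds (default 5).
#' @param seed Master seed controlling fold assignment and subsampling.
#' @param model `"relm"` or `"lm"`.
#' @param ratio Event ratio of the training subsample (relm only).
#' @param method Correction method (relm only).
#' @param bias_correct Apply the coefficient bias correction (relm only).
#' @return A list with `mean_auc`, `fold_auc` (length K) and `folds` (the
#'   fold assignment vector).
#' @export
kfold_auc <- function(data, K = 5L, seed = 1L, model = c("relm", "lm"),
                      ratio = 0.43, method = c("weighting", "prior"),
                      bias_correct = TRUE) {
  stopifnot(inherits(data, "crash_dataset"))
  model <- match.arg(model)
  method <- match.arg(method)
  fold <- stratified_folds(data$y, K, seed)
  fold_auc <- numeric(K)
  for (k in seq_len(K)) {
    train <- subset_dataset(data, fold != k)
    valid <- subset_dataset(data, fold == k)
    if (model == "lm") {
      red <- drop_unidentifiable(train)
      fit <- fit_logit(red$data)
      scores <- plogis(drop(valid$X[, red$kept, drop = FALSE] %*% fit$beta))
    } else {
      ss <- case_based_subsample(train, ratio, seed = derive_seed(seed, k))
      rf <- fit_relm_pipeline(ss$sample, ss$info, method,
                              bias_correct = bias_correct,
                              column_names = train$column_names)
      scores <- corrected_probability(rf, valid)$p
    }
    fold_auc[k] <- roc_curve(scores, valid$y)$auc
  }
  list(mean_auc = mean(fold_auc), fold_auc = fold_auc, folds = fold)
}

#' Event-ratio sweep
#'
#' For every event ratio on the grid: draw one choice-based subsample (a
#' fresh seed per grid point derived from the master seed), fit and correct
#' with each requested method, predict on the full population, and record
#' ACR and FCR at `threshold` together with the trapezoidal AUC.
#'
#' Classification uses the sample-scale corrected probabilities (see
#' [corrected_probability()]): the rare-events fit flags a record as fatal
#' when its probability on the training event-ratio scale exceeds the
#' threshold, which is how the published classification counts of such
#' models arise.  The AUC is computed from the population-scale corrected
#' probabilities (AUC is unaffected by the monotone intercept shift).
#'
#' @param data A [crash_dataset()] (the full population).
#' @param grid Strictly increasing event-ratio grid inside (population
#'   event fraction, 1); default `seq(0.05, 0.95, by = 0.01)`, 91 points.
#' @param methods Character subset of `c("prior", "weighting")`.
#' @param threshold Classification threshold (default 0.5).
#' @param seed Master seed.
#' @param bias_correct Apply the coefficient bias correction.
#' @return A `sweep_result`: a data frame with columns `ratio`, `method`,
#'   `acr`, `fcr`, `auc`, `seed`.  Grid points whose fit fails (e.g.
#'   separation when almost no non-events remain near the top of the grid)
#'   are recorded as `NA` with a warning rather than aborting the sweep.
#' @export
ratio_sweep <- function(data, grid = seq(0.05, 0.95, by = 0.01),
                        methods = c("prior", "weighting"), threshold = 0.5,
                        seed = 1L, bias_correct = TRUE) {
  stopifnot(inherits(data, "crash_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  pop_rate <- mean(data$y)
  if (any(grid <= pop_rate) || any(grid >= 1)) {
    stop("grid must lie strictly between the population event fraction (",
         format(pop_rate, digits = 4), ") and 1")
  }
  rows <- vector("list", length(grid) * length(methods))
  r <- 0L
  for (i in seq_along(grid)) {
    seed_i <- derive_seed(seed, i)
    ss <- case_based_subsample(data, grid[i], seed = seed_i)
    for (method in methods) {
      r <- r + 1L
      rows[[r]] <- tryCatch({
        rf <- fit_relm_pipeline(ss$sample, ss$info, method,
                                bias_correct = bias_correct,
                                column_names = data$column_names)
        score_cls <- corrected_probability(rf, data, scale = "sample")$p
        score_auc <- corrected_probability(rf, data, scale = "population")$p
        cm <- confusion(classify(score_cls, threshold), data$y)
        data.frame(ratio = grid[i], method = method,
                   acr = cm$acr, fcr = cm$fcr,
                   auc = roc_curve(score_auc, data$y)$auc,
                   seed = seed_i)
      }, error = function(e) {
        ## at the extreme top of the grid the subsample can hold so few
        ## non-events that the fit separates; record the point as missing
        ## rather than abort the whole sweep
        warning("ratio ", format(grid[i]), " (", method, ") failed: ",
                conditionMessage(e), call. = FALSE)
        data.frame(ratio = grid[i], method = method,
                   acr = NA_real_, fcr = NA_real_, auc = NA_real_,
                   seed = seed_i)
      })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "master_seed") <- seed
  out
}
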