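## Estimation core: logistic MLE by Newton/IRLS with step-halving, the
## prior and weighting corrections for choice-based sampling, the
## weighted-least-squares finite-sample bias correction, and the
## second-order corrected event probability.

weighted_loglik <- function(X, beta, y, w) {
  eta <- drop(X %*% beta)
  ## -sum_i w_i log(1 + exp((1 - 2 y_i) eta_i))
  -sum(w * softplus((1 - 2 * y) * eta))
}

## Newton iteration with step-halving on the (weighted) Bernoulli
## log-likelihood.  Deterministic; converges when max |gradient| < tol.
logit_irls <- function(X, y, w, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  ll <- weighted_loglik(X, beta, y, w)
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(X %*% beta)
    pi <- plogis(eta)
    grad <- drop(crossprod(X, w * (y - pi)))
    if (max(abs(grad)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    Wd <- w * pi * (1 - pi)
    H <- crossprod(X, X * Wd)
    delta <- tryCatch(solve(H, grad), error = function(e) {
      stop("observed information matrix is singular; check the design ",
           "for collinear or constant columns", call. = FALSE)
    })
    ## accept any step that does not decrease the log-likelihood beyond
    ## rounding noise, so Newton can traverse the flat region at the optimum
    noise <- 1e-10 * (abs(ll) + 1)
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      ll_new <- weighted_loglik(X, beta_new, y, w)
      if (ll_new >= ll - noise || step < 1e-10) break
      step <- step / 2
    }
    if (max(abs(beta_new)) > 30 && ll_new >= ll) {
      stop("complete or quasi-complete separation detected ",
           "(coefficients diverging beyond 30 with improving likelihood)",
           call. = FALSE)
    }
    beta <- beta_new
    ll <- ll_new
  }
  if (!converged) {
    stop("IRLS did not converge within ", max_iter, " iterations ",
         "(max |gradient| = ", format(max(abs(grad)), digits = 4), ")",
         call. = FALSE)
  }
  list(beta = setNames(beta, colnames(X)), loglik = ll,
       fitted = plogis(drop(X %*% beta)),
       iterations = iter, grad_norm = max(abs(grad)))
}

check_design_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear or constant column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

logit_cov <- function(X, pi, w, y, cov_type) {
  H <- crossprod(X, X * (w * pi * (1 - pi)))
  Hinv <- solve(H)
  if (cov_type == "sandwich") {
    B <- crossprod(X, X * (w^2 * (y - pi)^2))
    Hinv %*% B %*% Hinv
  } else {
    Hinv
  }
}

new_logit_fit <- function(res, X, y, w, weighted, info, cov_type) {
  cov <- logit_cov(X, res$fitted, w, y, cov_type)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(beta = res$beta, cov = cov, loglik = res$loglik,
                 weighted = weighted, sample_info = info,
                 converged = TRUE, iterations = res$iterations,
                 grad_norm = res$grad_norm, fitted = res$fitted,
                 cov_type = cov_type, n = nrow(X), k = ncol(X) - 1L),
            class = "logit_fit")
}

#' Maximum-likelihood logistic regression
#'
#' Fits \eqn{\Pr(y_i = 1) = \sigma(X_i \beta)} by maximising the Bernoulli
#' likelihood with Newton/IRLS steps and step-halving.  The covariance is
#' the inverse observed information
#' \eqn{(X' \mathrm{diag}(\hat\pi(1-\hat\pi)) X)^{-1}}; for a single
#' coefficient this reduces to the familiar scalar variance
#' \eqn{1/\sum_i \pi_i(1-\pi_i)x_i^2}.
#'
#' @param data A [crash_dataset()]; the design must be full column rank and
#'   both outcome classes must be present.
#' @param cov_type `"hessian"` (inverse observed information, default) or
#'   `"sandwich"` (robust).
#' @param max_iter,tol Iteration cap and gradient convergence tolerance.
#' @return An object of class `logit_fit` with fields `beta`, `cov`,
#'   `loglik`, `weighted`, `converged`, `iterations`, `fitted`.
#' @export
fit_logit <- function(data, cov_type = c("hessian", "sandwich"),
                      max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(data, "crash_dataset"))
  cov_type <- match.arg(cov_type)
  if (length(unique(data$y)) < 2L) {
    stop("outcome has a single class; the model is inestimable ",
         "(complete separation)", call. = FALSE)
  }
  check_design_rank(data$X)
  w <- rep(1, data$n)
  res <- logit_irls(data$X, data$y, w, max_iter = max_iter, tol = tol)
  new_logit_fit(res, data$X, data$y, w, weighted = FALSE, info = NULL,
                cov_type = cov_type)
}

#' Weighted maximum-likelihood logit (weighting correction)
#'
#' Maximises the case-control weighted log-likelihood
#' \deqn{\ln L_w(\beta) = \omega_1 \sum_{y_i=1} \ln \pi_i +
#'   \omega_0 \sum_{y_i=0} \ln(1-\pi_i)}
#' with \eqn{\omega_1 = \tau/\bar y} and
#' \eqn{\omega_0 = (1-\tau)/(1-\bar y)}, which undoes the intercept
#' distortion of choice-based sampling: an intercept-only weighted fit
#' returns \eqn{\mathrm{logit}(\tau)}.  With \eqn{\tau = \bar y} all weights
#' are one and the fit coincides with [fit_logit()].
#'
#' The default covariance is the inverse Hessian of the weighted
#' log-likelihood; `cov_type = "sandwich"` gives the robust
#' pseudo-likelihood alternative.
#'
#' @param data A [crash_dataset()].
#' @param info A [sample_info()] carrying \eqn{\tau} and \eqn{\bar y}.
#' @inheritParams fit_logit
#' @return A `logit_fit` with `weighted = TRUE` and `sample_info` attached.
#' @export
fit_weighted_logit <- function(data, info, cov_type = c("hessian", "sandwich"),
                               max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(data, "crash_dataset"), inherits(info, "sample_info"))
  cov_type <- match.arg(cov_type)
  if (length(unique(data$y)) < 2L) {
    stop("outcome has a single class; the model is inestimable ",
         "(complete separation)", call. = FALSE)
  }
  check_design_rank(data$X)
  w <- record_weights(info, data$y)
  res <- logit_irls(data$X, data$y, w, max_iter = max_iter, tol = tol)
  new_logit_fit(res, data$X, data$y, w, weighted = TRUE, info = info,
                cov_type = cov_type)
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit>%s n=%d, %d coefficients, loglik=%.4f (%d iterations)\n",
              if (x$weighted) " weighted," else "", x$n, length(x$beta),
              x$loglik, x$iterations))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.logit_fit <- function(object, ...) object$beta

#' @export
vcov.logit_fit <- function(object, ...) object$cov

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

#' Offset removed from the intercept by the prior correction
#'
#' @param info A [sample_info()].
#' @return \eqn{\ln[((1-\tau)/\tau)(\bar y/(1-\bar y))]}.
#' @export
prior_offset <- function(info) {
  stopifnot(inherits(info, "sample_info"))
  log(((1 - info$tau) / info$tau) * (info$ybar / (1 - info$ybar)))
}

#' Prior correction of the intercept
#'
#' Shifts the intercept of a fit obtained on a choice-based sample back to
#' the population scale:
#' \deqn{\beta_0 = \hat\beta_0 - \ln[((1-\tau)/\tau)(\bar y/(1-\bar y))].}
#' Slope coefficients and the covariance are left untouched — under
#' choice-based sampling the slopes remain statistically consistent; only
#' the intercept absorbs the sampling distortion.
#'
#' @param fit A converged unweighted `logit_fit`.
#' @param info A [sample_info()].
#' @return A `logit_fit` with the adjusted intercept and a `prior_offset`
#'   field recording the shift.
#' @export
prior_correct_intercept <- function(fit, info) {
  stopifnot(inherits(fit, "logit_fit"), inherits(info, "sample_info"))
  if (!fit$converged) stop("fit did not converge")
  off <- prior_offset(info)
  fit$beta[1L] <- fit$beta[1L] - off
  fit$prior_offset <- off
  fit$fitted <- NULL  # fitted values of the uncorrected fit no longer apply
  fit$sample_info <- info
  fit
}

#' Finite-sample coefficient bias of a logistic fit
#'
#' Evaluates the weighted-least-squares estimate of the
#' \eqn{O(1/n)} coefficient bias,
#' \deqn{\mathrm{bias}(\hat\beta) = (X'WX)^{-1} X' W \xi,}
#' where \eqn{W = \mathrm{diag}\{\hat\pi_i(1-\hat\pi_i)\omega_i\}},
#' \eqn{\xi_i = 0.5\, Q_{ii} ((1+\omega_1)\hat\pi_i - \omega_1)} and
#' \eqn{Q_{ii}} are the diagonal entries of
#' \eqn{Q = X (X'WX)^{-1} X'}.  For an unweighted fit
#' \eqn{\omega_1 = \omega_0 = 1}, in which case an intercept-only model has
#' the closed-form bias \eqn{(\hat\pi - 0.5)/(n\hat\pi(1-\hat\pi))}.
#'
#' @param fit A converged `logit_fit` obtained on `data`.
#' @param data The [crash_dataset()] the fit was computed on.
#' @param info A [sample_info()]; required when `fit` is weighted, ignored
#'   otherwise.
#' @return An object of class `bias_correction` with fields `xi`, `q_diag`,
#'   `w_diag` and `bias`.
#' @export
estimate_coefficient_bias <- function(fit, data, info = NULL) {
  stopifnot(inherits(fit, "logit_fit"), inherits(data, "crash_dataset"))
  if (!fit$converged) stop("fit did not converge")
  X <- data$X
  if (ncol(X) != length(fit$beta)) stop("fit and data are not column-compatible")
  pi <- plogis(drop(X %*% fit$beta))
  if (fit$weighted) {
    info <- info %||% fit$sample_info
    if (is.null(info)) stop("a weighted fit needs `info` for the bias weights")
    w <- record_weights(info, data$y)
    omega1 <- info$omega1
  } else {
    w <- rep(1, data$n)
    omega1 <- 1
  }
  Wd <- pi * (1 - pi) * w
  XtWX <- crossprod(X, X * Wd)
  A <- tryCatch(solve(XtWX), error = function(e) {
    stop("X'WX is singular; bias correction is unavailable", call. = FALSE)
  })
  q_diag <- rowSums((X %*% A) * X)
  xi <- 0.5 * q_diag * ((1 + omega1) * pi - omega1)
  bias <- drop(A %*% crossprod(X, Wd * xi))
  structure(list(xi = xi, q_diag = q_diag, w_diag = Wd,
                 bias = setNames(bias, colnames(X))),
            class = "bias_correction")
}

#' Fully corrected rare-events fit
#'
#' Applies the selected sampling correction and then subtracts the
#' finite-sample coefficient bias, \eqn{\tilde\beta = \hat\beta -
#' \mathrm{bias}(\hat\beta)}:
#' \itemize{
#'   \item `method = "prior"`: takes an *unweighted* fit on the subsample,
#'     estimates the bias at its fitted probabilities (unit weights), and
#'     shifts the intercept by [prior_offset()];
#'   \item `method = "weighting"`: takes a *weighted* fit
#'     ([fit_weighted_logit()]), whose intercept is already on the
#'     population scale, and estimates the bias with the case-control
#'     weights.
#' }
#' The covariance of \eqn{\tilde\beta} uses degrees-of-freedom shrinkage of
#' the base covariance, \eqn{V(\tilde\beta) = (n/(n+k+1))^2 V(\hat\beta)}.
#'
#' @param fit A converged `logit_fit` on `data` (unweighted for
#'   `method = "prior"`, weighted for `method = "weighting"`).
#' @param data The [crash_dataset()] the fit was computed on.
#' @param info A [sample_info()].
#' @param method `"prior"` or `"weighting"`.
#' @param bias_correct Set `FALSE` to skip the coefficient bias subtraction.
#' @return An object of class `relm_fit` with fields `beta_tilde`,
#'   `cov_tilde`, `method`, `base` (the sampling-corrected `logit_fit`),
#'   `bias`, `sample_info` and `prior_offset`.
#' @export
correct_fit <- function(fit, data, info, method = c("prior", "weighting"),
                        bias_correct = TRUE) {
  stopifnot(inherits(fit, "logit_fit"), inherits(data, "crash_dataset"),
            inherits(info, "sample_info"))
  method <- match.arg(method)
  if (method == "prior" && fit$weighted) {
    stop("method = \"prior\" requires an unweighted fit")
  }
  if (method == "weighting" && !fit$weighted) {
    stop("method = \"weighting\" requires a weighted fit; see fit_weighted_logit()")
  }
  bias <- estimate_coefficient_bias(fit, data, info)
  base <- if (method == "prior") prior_correct_intercept(fit, info) else fit
  bvec <- if (bias_correct) bias$bias else setNames(numeric(length(fit$beta)),
                                                    names(fit$beta))
  beta_tilde <- base$beta - bvec
  m <- data$n
  p <- length(beta_tilde)
  cov_tilde <- (m / (m + p))^2 * base$cov
  structure(list(beta_tilde = beta_tilde, cov_tilde = cov_tilde,
                 method = method, base = base, bias = bias,
                 sample_info = info, prior_offset = prior_offset(info),
                 bias_corrected = bias_correct),
            class = "relm_fit")
}

#' @export
print.relm_fit <- function(x, ...) {
  cat(sprintf("<relm_fit> %s correction%s, %d coefficients\n",
              x$method, if (x$bias_corrected) " + bias correction" else "",
              length(x$beta_tilde)))
  print(round(x$beta_tilde, 4))
  invisible(x)
}

#' @export
coef.relm_fit <- function(object, ...) object$beta_tilde

#' @export
vcov.relm_fit <- function(object, ...) object$cov_tilde

#' Corrected event probabilities
#'
#' Computes \eqn{\tilde\pi_i = \sigma(X_i \tilde\beta)} and the
#' second-order probability correction
#' \deqn{C_i = (0.5 - \tilde\pi_i)\,\tilde\pi_i(1-\tilde\pi_i)\,
#'   X_i V(\tilde\beta) X_i',}
#' returning \eqn{P_i = \tilde\pi_i + C_i}.  Because
#' \eqn{\mathrm{sign}(C_i) = \mathrm{sign}(0.5 - \tilde\pi_i)}, rare events
#' (small \eqn{\tilde\pi}) receive non-negative corrections: estimation
#' uncertainty is converted into a lift of the underestimated rare-event
#' probability.  \eqn{P_i} is clamped to \eqn{[0,1]} with a warning if the
#' correction overshoots.
#'
#' @param fit A [correct_fit()] result.
#' @param data A [crash_dataset()] column-compatible with the fit.
#' @param scale `"population"` (default) evaluates the corrected
#'   coefficients as stored; `"sample"` adds back [prior_offset()] to the
#'   intercept first, giving probabilities on the event-ratio scale of the
#'   training subsample — the scale on which threshold classification of a
#'   rare-events fit is performed (see [ratio_sweep()]).
#' @return An object of class `relm_prediction` with fields `pi_hat` (from
#'   the uncorrected-bias coefficients), `pi_tilde`, `correction` and `p`.
#' @export
corrected_probability <- function(fit, data,
                                  scale = c("population", "sample")) {
  stopifnot(inherits(fit, "relm_fit"), inherits(data, "crash_dataset"))
  scale <- match.arg(scale)
  X <- data$X
  if (ncol(X) != length(fit$beta_tilde) ||
      !identical(colnames(X), names(fit$beta_tilde))) {
    stop("fit and data are not column-compatible")
  }
  shift <- if (scale == "sample") fit$prior_offset else 0
  eta <- drop(X %*% fit$beta_tilde) + shift
  pi_tilde <- plogis(eta)
  quad <- rowSums((X %*% fit$cov_tilde) * X)
  correction <- (0.5 - pi_tilde) * pi_tilde * (1 - pi_tilde) * quad
  p <- pi_tilde + correction
  n_clamp <- sum(p < 0 | p > 1)
  if (n_clamp > 0) {
    warning(n_clamp, " corrected probabilit",
            if (n_clamp == 1) "y" else "ies", " clamped to [0, 1]")
    p <- pmin(pmax(p, 0), 1)
  }
  pi_hat <- plogis(drop(X %*% fit$base$beta) + shift)
  structure(list(pi_hat = pi_hat, pi_tilde = pi_tilde,
                 correction = correction, p = p, scale = scale),
            class = "relm_prediction")
}

#' Predicted probabilities of a plain logistic fit on new data
#'
#' @param object A `logit_fit`.
#' @param data A [crash_dataset()] column-compatible with the fit.
#' @param ... Unused.
#' @return Numeric vector \eqn{\sigma(X\hat\beta)}.
#' @export
predict.logit_fit <- function(object, data, ...) {
  stopifnot(inherits(data, "crash_dataset"))
  if (ncol(data$X) != length(object$beta)) {
    stop("fit and data are not column-compatible")
  }
  plogis(drop(data$X %*% object$beta))
}
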