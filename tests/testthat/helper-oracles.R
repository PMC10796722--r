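## Independent oracles and fixture builders shared across the test files.
## Everything here is deliberately naive: plain-formula likelihoods, dense
## matrix algebra, pair counting -- kept separate from the package's own
## computational paths.

## naive Bernoulli log-likelihood (weighted); the direct product formula
oracle_loglik <- function(beta, X, y, w = rep(1, length(y))) {
  p <- plogis(drop(X %*% beta))
  sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

## brute-force numerical maximisation of the (weighted) likelihood
oracle_mle <- function(X, y, w = rep(1, length(y))) {
  fn <- function(b) -oracle_loglik(b, X, y, w)
  fit <- optim(numeric(ncol(X)), fn, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit2 <- optim(fit$par, fn, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-14))
  fit2$par
}

## Mann-Whitney pair-counting AUC: concordant + half ties over all
## event/non-event pairs
oracle_auc <- function(p, y) {
  p1 <- p[y == 1]
  p0 <- p[y == 0]
  cmp <- outer(p1, p0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## dense-matrix evaluation of the weighted-least-squares coefficient bias
oracle_bias <- function(X, beta, y, omega1 = 1, omega0 = 1) {
  pi <- plogis(drop(X %*% beta))
  w <- omega1 * y + omega0 * (1 - y)
  W <- diag(pi * (1 - pi) * w, nrow = length(y))
  XtWX <- t(X) %*% W %*% X
  Q <- X %*% solve(XtWX) %*% t(X)
  xi <- 0.5 * diag(Q) * ((1 + omega1) * pi - omega1)
  unname(drop(solve(XtWX) %*% t(X) %*% W %*% xi))
}

## hand-built dataset from a design matrix (adds the constant column)
make_ds <- function(y, ..., frame = NULL) {
  dots <- list(...)
  n <- length(y)
  X <- cbind("(Intercept)" = rep(1, n))
  for (nm in names(dots)) {
    X <- cbind(X, as.numeric(dots[[nm]]))
    colnames(X)[ncol(X)] <- nm
  }
  crash_dataset(y, X, frame = frame)
}

## intercept-only dataset with n1 events among n rows
counts_ds <- function(n1, n) {
  make_ds(c(rep(1L, n1), rep(0L, n - n1)))
}

## a small three-factor generator spec with a non-rare event rate, for
## fast end-to-end runs
mini_spec <- function(n = 4000, rate = 0.05, seed = 1L) {
  generator_spec(
    factors = list(
      factor_spec("a", c("a0", "a1"), c(0.7, 0.3)),
      factor_spec("b", c("b0", "b1", "b2"), c(0.5, 0.3, 0.2)),
      factor_spec("c", c("c0", "c1"), c(0.6, 0.4))
    ),
    coefficients = c("a=a1" = 1.2, "b=b2" = -0.8, "c=c1" = 0.5),
    target_event_rate = rate, n = n, seed = seed
  )
}

## a fixed 20-row two-covariate fixture with both classes and no separation
fixture20 <- function() {
  x1 <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0, 1, 0, 1, 0, 0)
  x2 <- c(0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 0, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  y  <- c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0, 0, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  make_ds(y, x1 = x1, x2 = x2)
}
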