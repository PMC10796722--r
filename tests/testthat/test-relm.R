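test_that("intercept-only fits return the logit of the event fraction", {
  ds <- counts_ds(50, 100)
  expect_equal(unname(fit_logit(ds)$beta), 0, tolerance = 1e-8)

  ds <- counts_ds(363, 107464)
  f <- fit_logit(ds)
  expect_equal(unname(f$beta), log(363 / 107101), tolerance = 1e-8)
  ## scalar information: V = 1 / sum(pi (1 - pi))
  pi <- 363 / 107464
  expect_equal(unname(f$cov[1, 1]), 1 / (107464 * pi * (1 - pi)),
               tolerance = 1e-6)
})

test_that("a single binary covariate recovers the 2x2 log odds ratio", {
  ## cells: (y=1,x=1)=10, (y=0,x=1)=90, (y=1,x=0)=2, (y=0,x=0)=98
  x <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(1, 10), rep(0, 90), rep(1, 2), rep(0, 98))
  f <- fit_logit(make_ds(y, x = x))
  expect_equal(unname(f$beta["x"]), log((10 * 98) / (90 * 2)),
               tolerance = 1e-7)
})

test_that("MLE matches brute-force likelihood maximisation on small fixtures", {
  ds <- fixture20()
  f <- fit_logit(ds)
  expect_equal(unname(f$beta), oracle_mle(ds$X, ds$y), tolerance = 1e-4)
  expect_lt(f$grad_norm, 1e-8)
  ## and matches glm on the same data
  g <- glm(ds$y ~ ds$X - 1, family = binomial)
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$cov), unname(vcov(g)), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("weighted MLE matches its brute-force and glm oracles", {
  ds <- fixture20()
  info <- sample_info(tau = 0.1, ybar = mean(ds$y))
  wf <- fit_weighted_logit(ds, info)
  w <- record_weights(info, ds$y)
  expect_equal(unname(wf$beta), oracle_mle(ds$X, ds$y, w), tolerance = 1e-4)
  g <- suppressWarnings(glm(ds$y ~ ds$X - 1, family = binomial, weights = w))
  expect_equal(unname(wf$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(wf$loglik, oracle_loglik(wf$beta, ds$X, ds$y, w),
               tolerance = 1e-8)
})

test_that("identity weights reduce the weighted fit to the plain fit", {
  ds <- fixture20()
  info <- sample_info(tau = mean(ds$y), ybar = mean(ds$y))
  expect_equal(fit_weighted_logit(ds, info)$beta, fit_logit(ds)$beta,
               tolerance = 1e-8)
})

test_that("weighted intercept-only fit returns logit(tau)", {
  ds <- counts_ds(43, 100)  # ybar = 0.43
  info <- sample_info(tau = 0.0034, ybar = 0.43)
  wf <- fit_weighted_logit(ds, info)
  expect_equal(unname(wf$beta), qlogis(0.0034), tolerance = 1e-6)
})

test_that("degenerate and ill-posed designs error informatively", {
  expect_error(fit_logit(make_ds(rep(1L, 20))), "single class")
  ## collinear columns are named
  x <- rep(c(0, 1), 10)
  ds <- make_ds(rep(c(0L, 1L, 1L, 0L), 5), x1 = x, x2 = x)
  expect_error(fit_logit(ds), "x2")
  ## perfectly separating covariate
  y <- rep(c(0L, 1L), 10)
  expect_error(fit_logit(make_ds(y, x = y)), "separation")
})

test_that("prior correction shifts only the intercept by the log ratio", {
  ds <- fixture20()
  f <- fit_logit(ds)
  info <- sample_info(tau = 0.0034, ybar = 0.43)
  pc <- prior_correct_intercept(f, info)
  off <- log((0.9966 / 0.0034) * (0.43 / 0.57))
  expect_equal(unname(pc$beta[1]), unname(f$beta[1]) - off)
  expect_equal(pc$beta[-1], f$beta[-1])
  expect_identical(pc$cov, f$cov)
  ## tau = ybar leaves the fit unchanged
  same <- prior_correct_intercept(f, sample_info(0.3, 0.3))
  expect_equal(same$beta, f$beta)
  ## swapping tau and ybar negates the offset
  expect_equal(prior_offset(sample_info(0.43, 0.0034)), -off)
})

test_that("coefficient bias matches closed forms and the dense oracle", {
  ## intercept-only, n=100, pi-hat = 0.2: bias = (pi-0.5)/(n pi (1-pi))
  ds <- counts_ds(20, 100)
  f <- fit_logit(ds)
  bc <- estimate_coefficient_bias(f, ds)
  pihat <- f$fitted[1]
  expect_equal(unname(bc$bias), (pihat - 0.5) / (100 * pihat * (1 - pihat)),
               tolerance = 1e-12)
  expect_equal(unname(bc$bias), (0.2 - 0.5) / (100 * 0.2 * 0.8),
               tolerance = 1e-7)
  ## balanced: zero bias
  ds5 <- counts_ds(50, 100)
  expect_equal(unname(estimate_coefficient_bias(fit_logit(ds5), ds5)$bias), 0,
               tolerance = 1e-12)
  ## small two-covariate fixture against naive dense-matrix evaluation
  ds <- fixture20()
  f <- fit_logit(ds)
  bc <- estimate_coefficient_bias(f, ds)
  expect_equal(unname(bc$bias), oracle_bias(ds$X, f$beta, ds$y),
               tolerance = 1e-10)
  ## weighted variant
  info <- sample_info(tau = 0.2, ybar = mean(ds$y))
  wf <- fit_weighted_logit(ds, info)
  bcw <- estimate_coefficient_bias(wf, ds, info)
  expect_equal(unname(bcw$bias),
               oracle_bias(ds$X, wf$beta, ds$y, info$omega1, info$omega0),
               tolerance = 1e-10)
  expect_true(all(bcw$w_diag >= 0))
  expect_true(all(bcw$q_diag >= 0))
})

test_that("bias halves when every observation is duplicated", {
  ds <- fixture20()
  f <- fit_logit(ds)
  b1 <- estimate_coefficient_bias(f, ds)$bias
  ds2 <- crash_dataset(rep(ds$y, 2), rbind(ds$X, ds$X))
  f2 <- fit_logit(ds2)
  expect_equal(f2$beta, f$beta, tolerance = 1e-7)
  b2 <- estimate_coefficient_bias(f2, ds2)$bias
  expect_equal(b2, b1 / 2, tolerance = 1e-8)
})

test_that("correct_fit applies the exact correction identities", {
  ds <- fixture20()
  info <- sample_info(tau = 0.1, ybar = mean(ds$y))
  f <- fit_logit(ds)
  rf <- correct_fit(f, ds, info, method = "prior")
  ## beta_tilde + bias = sampling-corrected beta, exactly
  expect_equal(rf$beta_tilde + rf$bias$bias, rf$base$beta)
  ## covariance shrinkage factor (n/(n+k+1))^2
  p <- length(rf$beta_tilde)
  expect_equal(rf$cov_tilde, (ds$n / (ds$n + p))^2 * rf$base$cov)
  ## method/fit mismatches error
  wf <- fit_weighted_logit(ds, info)
  expect_error(correct_fit(wf, ds, info, method = "prior"), "unweighted")
  expect_error(correct_fit(f, ds, info, method = "weighting"), "weighted fit")
  ## bias_correct = FALSE only applies the sampling correction
  rf0 <- correct_fit(f, ds, info, method = "prior", bias_correct = FALSE)
  expect_equal(rf0$beta_tilde, rf0$base$beta)
})

test_that("prior and weighting corrections agree on the full population", {
  ## no subsampling: tau = ybar, weights 1 -- both corrections must
  ## collapse onto the bias-corrected plain MLE
  pop <- generate_population(mini_spec(n = 3000, rate = 0.2), seed = 8)
  info <- sample_info(tau = mean(pop$y), ybar = mean(pop$y))
  f <- fit_logit(pop)
  rf_p <- correct_fit(f, pop, info, method = "prior")
  rf_w <- correct_fit(fit_weighted_logit(pop, info), pop, info,
                      method = "weighting")
  mle_minus_bias <- f$beta - estimate_coefficient_bias(f, pop)$bias
  expect_equal(rf_p$beta_tilde, mle_minus_bias, tolerance = 1e-8)
  expect_equal(rf_w$beta_tilde, mle_minus_bias, tolerance = 1e-6)
})

test_that("bias vanishes asymptotically", {
  pop <- generate_population(mini_spec(n = 60000, rate = 0.3), seed = 2)
  info <- sample_info(tau = mean(pop$y), ybar = mean(pop$y))
  f <- fit_logit(pop)
  rf <- correct_fit(f, pop, info, method = "prior")
  expect_lt(max(abs(rf$beta_tilde - f$beta)), 1e-3)
})

test_that("corrected probabilities follow the second-order formula", {
  ds <- counts_ds(5, 10)
  info <- sample_info(tau = 0.5, ybar = 0.5)
  rf <- correct_fit(fit_logit(ds), ds, info, method = "prior")
  ## pi = 0.5 (balanced intercept-only): correction is exactly zero
  pr <- corrected_probability(rf, ds)
  expect_equal(unname(pr$pi_tilde), rep(0.5, 10), tolerance = 1e-8)
  expect_equal(unname(pr$correction), rep(0, 10), tolerance = 1e-10)
  ## zero covariance: P = pi_tilde
  rf0 <- rf
  rf0$cov_tilde <- matrix(0, 1, 1, dimnames = dimnames(rf$cov_tilde))
  pr0 <- corrected_probability(rf0, ds)
  expect_equal(pr0$p, pr0$pi_tilde)
  ## scalar worked case: pi = 0.1, V = 0.25 -> C = 0.009, P = 0.109
  rf1 <- rf
  rf1$beta_tilde[] <- qlogis(0.1)
  rf1$cov_tilde <- matrix(0.25, 1, 1, dimnames = dimnames(rf$cov_tilde))
  pr1 <- corrected_probability(rf1, ds)
  expect_equal(unname(pr1$correction), rep(0.4 * 0.1 * 0.9 * 0.25, 10),
               tolerance = 1e-12)
  expect_equal(unname(pr1$p), rep(0.109, 10), tolerance = 1e-12)
})

test_that("probability corrections lift rare-event predictions", {
  ## sign(C) = sign(0.5 - pi); with all pi < 0.5, mean(P) >= mean(pi)
  pop <- generate_population(mini_spec(n = 2500, rate = 0.05), seed = 13)
  ss <- case_based_subsample(pop, 0.4, seed = 13)
  rf <- correct_fit(fit_logit(ss$sample), ss$sample, ss$info,
                    method = "prior")
  pr <- corrected_probability(rf, pop)
  quad_pos <- rowSums((pop$X %*% rf$cov_tilde) * pop$X) > 0
  expect_true(all(sign(pr$correction[quad_pos]) ==
                  sign(0.5 - pr$pi_tilde[quad_pos])))
  low <- pr$pi_tilde < 0.5
  expect_true(all(pr$correction[low & quad_pos] >= 0))
  if (all(low)) expect_gte(mean(pr$p), mean(pr$pi_tilde))
})

test_that("naive subsampled intercepts are offset by the prior-correction log ratio", {
  ## over replicates, (naive intercept - true intercept) concentrates
  ## around log[((1-tau)/tau)(ybar/(1-ybar))]
  sp <- mini_spec(n = 8000, rate = 0.02)
  dev <- numeric(60)
  for (r in seq_along(dev)) {
    pop <- generate_population(sp, seed = 300 + r)
    ss <- case_based_subsample(pop, 0.4, seed = 600 + r)
    f <- fit_logit(ss$sample)
    dev[r] <- unname(f$beta[1]) - pop$truth$intercept - prior_offset(ss$info)
  }
  expect_lt(abs(mean(dev)), 4 * sd(dev) / sqrt(length(dev)) + 0.05)
})

test_that("sandwich covariance is available for the weighted fit", {
  ds <- fixture20()
  info <- sample_info(tau = 0.1, ybar = mean(ds$y))
  h <- fit_weighted_logit(ds, info)
  s <- fit_weighted_logit(ds, info, cov_type = "sandwich")
  expect_equal(h$beta, s$beta, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(h$cov, s$cov)))
  ## both symmetric positive semi-definite
  for (V in list(h$cov, s$cov)) {
    expect_equal(V, t(V), tolerance = 1e-10)
    expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-10))
  }
})
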