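test_that("classification is a strict threshold rule", {
  expect_identical(classify(c(0.2, 0.6), 0.5), c(0L, 1L))
  expect_identical(classify(c(0.2, 0.6, 1.0), 1), c(0L, 0L, 0L))
  expect_identical(classify(c(0.2, 0.6), 0), c(1L, 1L))
  expect_identical(classify(c(0.5), 0.5), 0L)  # strict inequality
  expect_error(classify(c(0.1), 1.5), "threshold")
})

test_that("confusion counts and rates follow their definitions", {
  cm <- confusion(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1))
  expect_equal(cm$true_positives, 2)
  expect_equal(cm$false_positives, 1)
  expect_equal(cm$acr, 2 / 3)
  expect_equal(cm$fcr, 1 / 2)
  expect_lte(cm$true_positives, min(cm$n_events, cm$n_predicted_events))
  ## perfect classifier
  cm <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(cm$acr, 1)
  expect_equal(cm$fcr, 0)
  expect_error(confusion(c(1, 0), c(1, 1)), "non-event")
  expect_error(confusion(c(1), c(1, 0)), "length")
})

test_that("ROC handles perfect separation and total ties", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  ## all scores tied: one diagonal segment, AUC 1/2
  r <- roc_curve(rep(0.3, 6), c(1, 0, 1, 0, 0, 0))
  expect_equal(r$auc, 0.5)
  expect_equal(r$tpr, c(0, 1))
  expect_equal(r$fpr, c(0, 1))
})

test_that("trapezoidal AUC equals the pair-counting concordance", {
  p8 <- c(0.9, 0.7, 0.7, 0.5, 0.4, 0.4, 0.2, 0.1)
  y8 <- c(1, 1, 0, 1, 0, 1, 0, 0)
  r <- roc_curve(p8, y8)
  expect_equal(r$auc, oracle_auc(p8, y8))
  ## random fixtures with heavy ties
  for (s in 1:5) {
    set.seed(s)
    p <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_curve(p, y)
    expect_equal(r$auc, oracle_auc(p, y), tolerance = 1e-12)
    ## curve is monotone with the right endpoints
    expect_true(all(diff(r$tpr) >= 0))
    expect_true(all(diff(r$fpr) >= 0))
    expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[1], 0)
    expect_equal(r$tpr[length(r$tpr)], 1)
    expect_equal(r$fpr[length(r$fpr)], 1)
  }
})

test_that("trapezoidal AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(21)
  p <- round(runif(200), 2)
  y <- rbinom(200, 1, plogis(3 * p - 1.5))
  ours <- roc_curve(p, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("raising the threshold never raises TPR or FPR", {
  set.seed(3)
  p <- runif(300)
  y <- rbinom(300, 1, p)
  prev <- NULL
  for (t in seq(0, 1, 0.1)) {
    cm <- confusion(classify(p, t), y)
    if (!is.null(prev)) {
      expect_lte(cm$acr, prev$acr + 1e-12)
      expect_lte(cm$fcr, prev$fcr + 1e-12)
    }
    prev <- cm
  }
})

test_that("stratified folds partition the data with balanced events", {
  y <- c(rep(1L, 363), rep(0L, 5000))
  fold <- crashrelm:::stratified_folds(y, 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), length(y))       # every record in one fold
  ev_counts <- table(fold[y == 1])
  expect_true(all(ev_counts %in% c(72, 73)))  # 363 = 5*72 + 3
  expect_error(crashrelm:::stratified_folds(c(1L, rep(0L, 50)), 5, 1),
               "fewer than K")
})

test_that("cross-validated AUC is reproducible and sane", {
  pop <- generate_population(mini_spec(n = 6000, rate = 0.05), seed = 4)
  a <- kfold_auc(pop, K = 5, seed = 9, model = "relm", ratio = 0.4,
                 method = "prior")
  b <- kfold_auc(pop, K = 5, seed = 9, model = "relm", ratio = 0.4,
                 method = "prior")
  expect_identical(a, b)
  expect_length(a$fold_auc, 5)
  expect_true(all(a$fold_auc >= 0 & a$fold_auc <= 1))
  expect_equal(a$mean_auc, mean(a$fold_auc))
  lm <- kfold_auc(pop, K = 5, seed = 9, model = "lm")
  expect_true(all(lm$fold_auc > 0.5))  # informative model beats chance
})

test_that("the event-ratio sweep is deterministic and well-formed", {
  pop <- generate_population(mini_spec(n = 6000, rate = 0.05), seed = 4)
  grid <- seq(0.1, 0.9, by = 0.1)
  a <- suppressWarnings(ratio_sweep(pop, grid = grid, seed = 17))
  b <- suppressWarnings(ratio_sweep(pop, grid = grid, seed = 17))
  expect_identical(a, b)
  expect_equal(nrow(a), length(grid) * 2)
  expect_setequal(unique(a$method), c("prior", "weighting"))
  expect_equal(sort(unique(a$ratio)), grid)
  ok <- !is.na(a$acr)
  expect_true(all(a$acr[ok] >= 0 & a$acr[ok] <= 1))
  expect_true(all(a$auc[ok] >= 0 & a$auc[ok] <= 1))
  ## both methods see the same subsample seed at each grid point
  expect_equal(a$seed[a$method == "prior"], a$seed[a$method == "weighting"])
  expect_error(ratio_sweep(pop, grid = c(0.01, 0.5)), "between")
  expect_error(ratio_sweep(pop, grid = c(0.5, 0.4)), "increasing")
})
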