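#' Describe one categorical risk factor
#'
#' A factor specification names a categorical covariate, lists its levels
#' (the first level is the reference level omitted from dummy coding) and
#' gives the marginal probability of each level.
#'
#' @param name Column name of the factor.
#' @param levels Character vector of at least two level labels; the first is
#'   the reference level.
#' @param probabilities Numeric vector of level probabilities, same length as
#'   `levels`, non-negative and summing to one (within `1e-9`).
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("sex", c("female", "male"), c(0.4364, 0.5636))
#' @export
factor_spec <- function(name, levels, probabilities) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    stop("a factor needs at least 2 levels, got ", length(levels))
  }
  if (anyDuplicated(levels)) stop("duplicated level labels in factor ", name)
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) != length(levels)) {
    stop("factor ", name, ": need one probability per level")
  }
  if (any(probabilities < 0)) stop("factor ", name, ": negative probability")
  if (abs(sum(probabilities) - 1) > 1e-9) {
    stop("factor ", name, ": probabilities sum to ",
         format(sum(probabilities), digits = 12), ", not 1")
  }
  structure(list(name = name, levels = levels,
                 probabilities = probabilities),
            class = "factor_spec")
}

dummy_names <- function(fac) paste0(fac$name, "=", fac$levels[-1L])

#' Marginal factor distribution of the emulated crash census
#'
#' Returns the sixteen driver, vehicle, roadway and environment factors of a
#' state-wide driver-vehicle crash census (107,464 units), with marginal
#' probabilities taken from its published frequency table.  For every factor
#' the reference level (first) is chosen so that the dummies reported by the
#' published risk-factor models are the non-reference levels.
#'
#' @return A named list of [factor_spec()] objects.
#' @export
florida_factor_specs <- function() {
  fs <- function(name, levels, counts) {
    factor_spec(name, levels, counts / sum(counts))
  }
  specs <- list(
    fs("age", c("25-65", "under-25", "above-65"), c(69677, 27685, 10102)),
    fs("sex", c("female", "male"), c(46897, 60567)),
    fs("alcohol", c("none", "drink-or-drugs"), c(103218, 4247)),
    fs("belt", c("used", "not-used"), c(101933, 5531)),
    fs("fault", c("at-fault", "not-at-fault"), c(44690, 62774)),
    fs("veh_year", c("pre-1996", "1996-2006"), c(25760, 81704)),
    fs("veh_type", c("passenger-car", "van", "light-truck", "heavy-truck"),
       c(73492, 8550, 21832, 3590)),
    fs("speed_ratio", c("above-1", "below-0.5", "0.5-1.0"),
       c(5147, 36676, 65641)),
    fs("poi", c("level-1", "level-2", "level-3", "level-4"),
       c(74949, 18381, 13816, 318)),
    fs("day", c("weekday", "weekend"), c(81930, 25534)),
    fs("location", c("urban", "rural"), c(57080, 50384)),
    fs("light", c("dark", "daylight"), c(25484, 81980)),
    fs("weather", c("clear", "not-clear"), c(79720, 27744)),
    fs("surface", c("dry", "not-dry"), c(94726, 12738)),
    fs("vision", c("not-obscured", "obscured"), c(99718, 7746)),
    fs("highway", c("divided", "undivided"), c(60014, 47450))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Generative log-odds effects of the emulated crash census
#'
#' Dummy-level effect sizes (log-odds) used as generative truth by the
#' default synthetic population.  Values follow the published rare-events
#' model of the emulated census: elevated fatality risk for drivers over 65,
#' alcohol/drug involvement, unbelted occupants, medium/heavy trucks,
#' near-driver points of impact and rural roads; reduced risk for newer
#' vehicles, sub-limit speeds, not-at-fault drivers and daylight.  Dummies
#' not listed (for example driver sex) have effect zero.
#'
#' @return Named numeric vector keyed by `"factor=level"` dummy names.
#' @export
florida_coefficients <- function() {
  c("age=above-65"          =  2.553,
    "alcohol=drink-or-drugs" = 1.854,
    "belt=not-used"         =  2.279,
    "veh_year=1996-2006"    = -0.415,
    "veh_type=heavy-truck"  =  0.492,
    "speed_ratio=below-0.5" = -1.703,
    "speed_ratio=0.5-1.0"   = -1.308,
    "poi=level-3"           =  1.536,
    "fault=not-at-fault"    = -2.609,
    "location=rural"        =  1.017,
    "light=daylight"        = -0.843)
}

#' Specify a synthetic crash population
#'
#' Bundles independent categorical factors, dummy-level effect sizes, an
#' intercept (either given directly or calibrated to a target event rate),
#' a population size and a seed.
#'
#' @param factors List of [factor_spec()] objects.
#' @param coefficients Named numeric vector of log-odds effects keyed by
#'   `"factor=level"`; every key must name a non-reference level of a listed
#'   factor.  Unlisted dummies have effect zero.
#' @param intercept Log-odds intercept, or `NULL` to calibrate.
#' @param target_event_rate Population event fraction in (0, 1) used to
#'   calibrate the intercept when `intercept` is `NULL`.
#' @param n Number of records to generate.
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @seealso [florida_generator_spec()] for the preconfigured census emulator.
#' @export
generator_spec <- function(factors, coefficients = numeric(),
                           intercept = NULL, target_event_rate = NULL,
                           n, seed = 1L) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  for (fac in factors) {
    if (!inherits(fac, "factor_spec")) stop("factors must be factor_spec objects")
  }
  fac_names <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(fac_names)) stop("duplicated factor names")
  names(factors) <- fac_names
  coefficients <- unlist(coefficients) %||% numeric()
  if (length(coefficients)) {
    valid <- unlist(lapply(factors, dummy_names))
    bad <- setdiff(names(coefficients), valid)
    if (length(bad)) {
      stop("coefficient keys do not name a (factor, non-reference level) pair: ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(intercept) == is.null(target_event_rate)) {
    stop("give exactly one of `intercept` and `target_event_rate`")
  }
  if (!is.null(target_event_rate)) {
    assert_fraction(target_event_rate, "target_event_rate")
  }
  if (!is.null(intercept)) stopifnot(is.numeric(intercept), is.finite(intercept))
  n <- as.integer(n)
  if (is.na(n) || n <= 0L) stop("`n` must be a positive integer")
  structure(list(factors = factors, coefficients = coefficients,
                 intercept = intercept, target_event_rate = target_event_rate,
                 n = n, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Preconfigured specification emulating the crash census
#'
#' Sixteen independent factors with the census marginals, the published
#' rare-events effect sizes as generative truth, and an intercept calibrated
#' so that the expected fatality rate matches the census rarity (0.34% by
#' default).
#'
#' @param n Population size (default: the census size, 107,464).
#' @param target_event_rate Target fatality fraction (default 0.0034).
#' @param seed Integer seed.
#' @param coefficients,factors Overrides for the generative truth.
#' @return A [generator_spec()].
#' @export
florida_generator_spec <- function(n = 107464L, target_event_rate = 0.0034,
                                   seed = 1L,
                                   coefficients = florida_coefficients(),
                                   factors = florida_factor_specs()) {
  generator_spec(factors = factors, coefficients = coefficients,
                 target_event_rate = target_event_rate, n = n, seed = seed)
}

## Exact discrete distribution of the non-intercept linear predictor,
## obtained by convolving per-factor effect distributions.  Factors whose
## levels all carry effect zero collapse to a point mass, so the table stays
## tiny even for many factors.
effect_distribution <- function(spec) {
  value <- 0
  prob <- 1
  for (fac in spec$factors) {
    eff <- setNames(numeric(length(fac$levels)), fac$levels)
    dn <- dummy_names(fac)
    hit <- intersect(names(spec$coefficients), dn)
    if (length(hit)) {
      eff[sub("^.*=", "", hit)] <- spec$coefficients[hit]
    }
    if (all(eff == 0)) next
    v <- as.vector(outer(value, eff, `+`))
    p <- as.vector(outer(prob, fac$probabilities, `*`))
    agg <- rowsum(p, group = round(v, 12))
    value <- as.numeric(rownames(agg))
    prob <- as.vector(agg)
    if (length(value) > 1e6) {
      stop("effect distribution has more than 1e6 support points; ",
           "cannot calibrate by exact enumeration")
    }
  }
  list(value = value, prob = prob)
}

#' Calibrate the intercept to a target event rate
#'
#' Finds the intercept \eqn{\beta_0} such that the exact expectation of the
#' event probability over the finite covariate distribution (enumerated with
#' its product probabilities — the factors are independent by construction)
#' equals `target_event_rate`.  Root finding is deterministic: bisection via
#' [stats::uniroot()] followed by Newton polishing, accurate to `1e-10`.
#'
#' @param spec A [generator_spec()] with a `target_event_rate`.
#' @return The calibrated intercept (log-odds scale).
#' @examples
#' sp <- generator_spec(list(factor_spec("x", c("a", "b"), c(0.5, 0.5))),
#'                      c("x=b" = 1), target_event_rate = 0.3, n = 10)
#' calibrate_intercept(sp)
#' @export
calibrate_intercept <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.null(spec$target_event_rate)) {
    if (!is.null(spec$intercept)) return(spec$intercept)
    stop("spec has no target_event_rate")
  }
  dist <- effect_distribution(spec)
  target <- spec$target_event_rate
  f <- function(b0) sum(dist$prob * plogis(b0 + dist$value)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target event rate ", target,
         " cannot be bracketed by the covariate-level distribution")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  for (i in 1:4) {
    fv <- f(root)
    dv <- sum(dist$prob * dlogis(root + dist$value))
    if (dv <= 0) break
    root <- root - fv / dv
  }
  root
}

assemble_beta <- function(column_names, intercept, coefficients) {
  beta <- setNames(numeric(length(column_names)), column_names)
  beta["(Intercept)"] <- intercept
  if (length(coefficients)) beta[names(coefficients)] <- coefficients
  beta
}

#' Generate a synthetic crash population
#'
#' Samples each factor independently from its marginal distribution, builds
#' the dummy-coded design matrix against the declared reference levels, and
#' draws the binary fatality outcome from a Bernoulli with logistic
#' probability \eqn{\sigma(X\beta)}.  The same seed gives a bit-identical
#' dataset.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A [crash_dataset()] whose `truth` field records the generative
#'   coefficient vector.
#' @export
generate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n
  if (n <= 0L) stop("`n` must be positive")
  set.seed(seed %||% spec$seed)
  frame <- as.data.frame(
    lapply(spec$factors, function(fac) {
      sample(fac$levels, n, replace = TRUE, prob = fac$probabilities)
    }),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(frame) <- names(spec$factors)
  X <- build_design(frame, spec$factors)
  b0 <- spec$intercept %||% calibrate_intercept(spec)
  beta <- assemble_beta(colnames(X), b0, spec$coefficients)
  eta <- drop(X %*% beta)
  y <- rbinom(n, 1L, plogis(eta))
  crash_dataset(y, X, frame = frame, factors = spec$factors,
                truth = list(beta = beta, intercept = b0))
}

#' Container for a dummy-coded crash dataset
#'
#' Holds the binary outcome vector, the design matrix with a leading
#' constant column and 0/1 dummy columns, and (when available) the raw
#' factor-level data frame it was expanded from.
#'
#' @param y Integer vector of 0/1 outcomes.
#' @param X Numeric design matrix, first column identically one, all other
#'   entries in \{0, 1\}; column names of the form `"factor=level"`.
#' @param frame Optional data frame of raw level labels (one column per
#'   factor), used for CSV round-trips and subsampling bookkeeping.
#' @param factors Optional list of [factor_spec()]s describing `frame`.
#' @param truth Optional list recording generative truth (synthetic data).
#' @return An object of class `crash_dataset` with fields `y`, `X`,
#'   `column_names`, `n`, `k`, `frame`, `factors`, `truth`.
#' @export
crash_dataset <- function(y, X, frame = NULL, factors = NULL, truth = NULL) {
  y <- as.integer(y)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must be 0/1")
  if (any(X[, 1L] != 1)) stop("first design column must be identically 1")
  if (ncol(X) > 1L && !all(X[, -1L] %in% c(0, 1))) {
    stop("non-intercept design entries must be 0/1 dummies")
  }
  if (is.null(colnames(X))) stop("design matrix must have column names")
  structure(list(y = y, X = X, column_names = colnames(X),
                 n = nrow(X), k = ncol(X) - 1L,
                 frame = frame, factors = factors, truth = truth),
            class = "crash_dataset")
}

#' @export
print.crash_dataset <- function(x, ...) {
  cat(sprintf("<crash_dataset> %d records, %d dummy columns, %d events (%.4f%%)\n",
              x$n, x$k, sum(x$y), 100 * mean(x$y)))
  invisible(x)
}

## Dummy-expand a data frame of level labels against a list of factor specs.
build_design <- function(frame, factors) {
  n <- nrow(frame)
  cols <- list("(Intercept)" = rep(1, n))
  for (fac in factors) {
    if (!fac$name %in% names(frame)) {
      stop("dataset is missing factor column `", fac$name, "`")
    }
    x <- frame[[fac$name]]
    unknown <- setdiff(unique(x), fac$levels)
    if (length(unknown)) {
      stop("column `", fac$name, "` contains unknown level(s): ",
           paste(unknown, collapse = ", "))
    }
    for (lev in fac$levels[-1L]) {
      cols[[paste0(fac$name, "=", lev)]] <- as.numeric(x == lev)
    }
  }
  do.call(cbind, cols)
}

subset_dataset <- function(data, idx) {
  crash_dataset(data$y[idx], data$X[idx, , drop = FALSE],
                frame = if (!is.null(data$frame)) data$frame[idx, , drop = FALSE],
                factors = data$factors, truth = data$truth)
}

#' Read / write a generator specification as JSON
#'
#' The JSON object carries `factors` (name, levels, probabilities),
#' `coefficients`, `n`, `seed`, and either `intercept` or
#' `target_event_rate`.
#'
#' @param spec A [generator_spec()].
#' @param path File path.
#' @return `read_generator_spec()` returns a [generator_spec()];
#'   `write_generator_spec()` returns `path` invisibly.
#' @export
write_generator_spec <- function(spec, path) {
  stopifnot(inherits(spec, "generator_spec"))
  obj <- list(
    factors = lapply(unname(spec$factors), function(f) {
      list(name = f$name, levels = f$levels, probabilities = f$probabilities)
    }),
    coefficients = as.list(spec$coefficients),
    n = spec$n, seed = spec$seed
  )
  if (!is.null(spec$intercept)) obj$intercept <- spec$intercept
  if (!is.null(spec$target_event_rate)) {
    obj$target_event_rate <- spec$target_event_rate
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  factors <- lapply(obj$factors, function(f) {
    factor_spec(f$name, unlist(f$levels), unlist(f$probabilities))
  })
  generator_spec(
    factors = factors,
    coefficients = unlist(obj$coefficients) %||% numeric(),
    intercept = obj$intercept,
    target_event_rate = obj$target_event_rate,
    n = obj$n, seed = obj$seed %||% 1L
  )
}
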