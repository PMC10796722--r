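#' Population/sample event fractions and case-control weights
#'
#' Bookkeeping object for choice-based sampling corrections: the population
#' event fraction \eqn{\tau}, the sample event fraction \eqn{\bar y}, and
#' the derived weights \eqn{\omega_1 = \tau/\bar y} for events and
#' \eqn{\omega_0 = (1-\tau)/(1-\bar y)} for non-events.  The per-record
#' weight is \eqn{\omega_i = \omega_1 y_i + \omega_0 (1-y_i)}.
#'
#' @param tau Event fraction in the full population, in (0, 1).
#' @param ybar Event fraction in the sample, in (0, 1).
#' @return An object of class `sample_info` with fields `tau`, `ybar`,
#'   `omega1`, `omega0`.
#' @export
sample_info <- function(tau, ybar) {
  assert_fraction(tau, "tau")
  assert_fraction(ybar, "ybar")
  structure(list(tau = tau, ybar = ybar,
                 omega1 = tau / ybar,
                 omega0 = (1 - tau) / (1 - ybar)),
            class = "sample_info")
}

#' @export
print.sample_info <- function(x, ...) {
  cat(sprintf("<sample_info> tau=%.6g  ybar=%.6g  omega1=%.6g  omega0=%.6g\n",
              x$tau, x$ybar, x$omega1, x$omega0))
  invisible(x)
}

#' Per-record case-control weights
#'
#' @param info A [sample_info()].
#' @param y 0/1 outcome vector.
#' @return Numeric vector \eqn{\omega_1 y + \omega_0 (1-y)}.
#' @export
record_weights <- function(info, y) {
  stopifnot(inherits(info, "sample_info"))
  info$omega1 * y + info$omega0 * (1 - y)
}

#' Choice-based (endogenous) subsample of a crash dataset
#'
#' Retains every event and draws a uniform without-replacement subsample of
#' non-events sized so that the event fraction of the result is close to
#' `target_event_ratio`: with \eqn{n_1} events the number of retained
#' non-events is \eqn{n_0 = \mathrm{round}(n_1 (1-r)/r)} (nearest integer,
#' ties to even).  The returned [sample_info()] stores \eqn{\tau} computed
#' from the input population and the realised \eqn{\bar y} of the sample —
#' all downstream corrections use the realised fraction, not the request.
#'
#' @param data A [crash_dataset()] with at least one event and one
#'   non-event.
#' @param target_event_ratio Requested event fraction, strictly between the
#'   population event fraction and 1.
#' @param seed Integer seed; the draw is reproducible.
#' @return A list with components `sample` (a [crash_dataset()]) and `info`
#'   (a [sample_info()]).
#' @examples
#' pop <- generate_population(florida_generator_spec(n = 20000, seed = 7))
#' ss <- case_based_subsample(pop, 0.43, seed = 7)
#' ss$info
#' @export
case_based_subsample <- function(data, target_event_ratio, seed) {
  stopifnot(inherits(data, "crash_dataset"))
  assert_fraction(target_event_ratio, "target_event_ratio")
  n1 <- sum(data$y == 1L)
  n0_avail <- sum(data$y == 0L)
  if (n1 < 1L) stop("dataset contains no events; nothing to retain")
  if (n0_avail < 1L) stop("dataset contains no non-events; cannot subsample")
  tau <- n1 / data$n
  if (target_event_ratio <= tau) {
    stop(sprintf(paste0("target event ratio (%.4g) must exceed the population ",
                        "event fraction (%.4g); achieving it would require ",
                        "discarding events"), target_event_ratio, tau))
  }
  n0 <- round(n1 * (1 - target_event_ratio) / target_event_ratio)
  if (n0 > n0_avail) {
    stop(sprintf("subsample needs %d non-events but only %d are available",
                 n0, n0_avail))
  }
  if (n0 < 1L) {
    stop("target event ratio leaves no non-events in the sample")
  }
  set.seed(seed)
  keep0 <- sample(which(data$y == 0L), n0)
  keep <- sort(c(which(data$y == 1L), keep0))
  smp <- subset_dataset(data, keep)
  info <- sample_info(tau = tau, ybar = n1 / (n1 + n0))
  list(sample = smp, info = info)
}
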