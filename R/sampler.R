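#' Row-stochastic probability matrix for multivariate categorical sampling
#'
#' One row per individual: row \eqn{k} holds that individual's interval
#' probabilities \eqn{p^k_0, \dots, p^k_Z}; `residual` holds the per-row
#' beyond-horizon mass. All rows share the interval width and horizon.
#'
#' @param probs numeric matrix, K rows by Z+1 columns, entries \eqn{\ge 0};
#'   each row must sum with its residual to 1 within `1e-9`.
#' @param delta_t shared interval width.
#' @param residual numeric vector of length K (recycled from length 1).
#' @param origin shared start time.
#' @return An object of class `"probability_matrix"`.
#' @seealso [sample_multivariate()], [probability_matrix_from_paths()]
#' @export
probability_matrix <- function(probs, delta_t = 1, residual = 0, origin = 0) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L || ncol(probs) < 1L)
    stop("'probs' must have at least one row and one column", call. = FALSE)
  if (anyNA(probs) || any(!is.finite(probs)) || any(probs < 0))
    stop("probabilities must be finite and >= 0", call. = FALSE)
  residual <- rep_len(as.numeric(residual), nrow(probs))
  if (any(!is.finite(residual)) || any(residual < 0))
    stop("'residual' must be finite and >= 0", call. = FALSE)
  tot <- rowSums(probs) + residual
  bad <- which(abs(tot - 1) > 1e-9)
  if (length(bad))
    stop("row ", bad[1L], " does not sum to 1 with its residual (sum = ",
         format(tot[bad[1L]], digits = 12), ")", call. = FALSE)
  check_delta_t(delta_t)
  structure(list(probs = probs, delta_t = as.numeric(delta_t),
                 residual = residual, origin = as.numeric(origin)),
            class = "probability_matrix")
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat(sprintf(
    "Probability matrix: %d individuals x %d intervals (width %g), max residual %.3g\n",
    nrow(x$probs), ncol(x$probs), x$delta_t, max(x$residual)))
  invisible(x)
}

new_event_times <- function(categories, delta_t, origin, corrected,
                            times = NULL) {
  structure(list(categories = categories, times = times,
                 delta_t = delta_t, origin = origin, corrected = corrected),
            class = "event_times")
}

#' Sampled event times
#'
#' @description
#' Draws from the discretized event-time distribution are objects of class
#' `"event_times"`: integer interval indices (`categories`, 0-based; `NA`
#' marks a beyond-horizon draw) and, after [continuous_time_correction()],
#' continuous times lying inside each draw's interval. `as.numeric()` returns
#' the continuous times when corrected, otherwise the interval start times.
#' `mean()` averages those values, excluding beyond-horizon sentinels.
#'
#' @param x,object an `"event_times"` object.
#' @param ... unused.
#' @name event_times
NULL

event_values <- function(x) {
  if (x$corrected) x$times else x$origin + x$categories * x$delta_t
}

#' @rdname event_times
#' @export
as.double.event_times <- function(x, ...) event_values(x)

#' @rdname event_times
#' @param na.rm ignored; beyond-horizon sentinels are always excluded.
#' @export
mean.event_times <- function(x, na.rm = TRUE, ...) {
  mean(event_values(x), na.rm = TRUE)
}

#' @rdname event_times
#' @export
length.event_times <- function(x) length(x$categories)

#' @rdname event_times
#' @export
print.event_times <- function(x, ...) {
  nb <- sum(is.na(x$categories))
  cat(sprintf("%d sampled event times (%s, delta_t = %g)",
              length(x$categories),
              if (x$corrected) "continuous-time corrected" else
                "interval categories only", x$delta_t))
  if (nb > 0) cat(sprintf(", %d beyond horizon", nb))
  cat("\n")
  invisible(x)
}

#' Number of beyond-horizon draws
#'
#' @param x an `"event_times"` object.
#' @return Count of draws that landed in the residual (no event by the grid
#'   horizon).
#' @export
n_beyond_horizon <- function(x) {
  stopifnot(inherits(x, "event_times"))
  sum(is.na(x$categories))
}

set_local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Draw event-time intervals from a single categorical distribution
#'
#' `n` independent draws with \eqn{P(X = t) = p_t} by inverse-CDF lookup on
#' the cumulative interval probabilities; a draw falling in the residual mass
#' returns the beyond-horizon sentinel (`NA` category).
#'
#' @param pmf an [event_pmf()].
#' @param n number of draws.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the draw is reproducible.
#' @return An uncorrected [event_times] object.
#' @examples
#' pmf <- event_pmf_from(hazard_grid(rep(0.1, 200)))
#' mean(continuous_time_correction(sample_univariate(pmf, 1e4, seed = 1),
#'                                 seed = 2))
#' @export
sample_univariate <- function(pmf, n, seed = NULL) {
  stopifnot(inherits(pmf, "event_pmf"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  set_local_seed(seed)
  cw <- cumsum(pmf$probs)
  u <- stats::runif(n)
  idx <- findInterval(u, cw)              # 0-based category
  idx[idx >= length(pmf$probs)] <- NA_integer_   # beyond horizon
  new_event_times(as.integer(idx), pmf$delta_t, pmf$origin, corrected = FALSE)
}

#' Draw one event-time interval per individual (multivariate categorical)
#'
#' One draw per row of a [probability_matrix()], independent across rows.
#' Exactly one uniform variate is consumed per row and mapped through that
#' row's cumulative interval probabilities (inverse CDF), so the whole
#' heterogeneous cohort is sampled in one vectorized pass.
#'
#' @param pm a [probability_matrix()].
#' @inheritParams sample_univariate
#' @return An uncorrected [event_times] object with one entry per row.
#' @export
sample_multivariate <- function(pm, seed = NULL) {
  stopifnot(inherits(pm, "probability_matrix"))
  set_local_seed(seed)
  cs <- pm$probs
  for (j in seq_len(ncol(cs))[-1L]) cs[, j] <- cs[, j] + cs[, j - 1L]
  u <- stats::runif(nrow(cs))
  idx <- rowSums(cs < u)                  # 0-based category per row
  idx[idx >= ncol(cs)] <- NA_integer_
  new_event_times(as.integer(idx), pm$delta_t, pm$origin, corrected = FALSE)
}

#' Correct interval draws back to continuous time
#'
#' Adds an independent \eqn{Y \sim U[0, \Delta t)} offset to every sampled
#' interval, placing the event uniformly inside its interval (consistent with
#' the piecewise-constant hazard). This raises the expected value by exactly
#' \eqn{\Delta t / 2} relative to the interval-start times, the continuous
#' analogue of a half-cycle correction. Beyond-horizon sentinels stay `NA`.
#'
#' @param draws an uncorrected [event_times] object.
#' @param seed optional integer seed for the uniform offsets; giving the
#'   correction its own seed keeps corrected and uncorrected summaries of the
#'   same draws pairable.
#' @return A corrected [event_times] object.
#' @export
continuous_time_correction <- function(draws, seed = NULL) {
  stopifnot(inherits(draws, "event_times"))
  if (draws$corrected)
    stop("draws are already corrected to continuous time", call. = FALSE)
  set_local_seed(seed)
  y <- stats::runif(length(draws$categories), 0, draws$delta_t)
  new_event_times(draws$categories, draws$delta_t, draws$origin,
                  corrected = TRUE,
                  times = draws$origin + draws$categories * draws$delta_t + y)
}

#' Exact expected event time of a discretized distribution
#'
#' \eqn{E[X \Delta t] = \sum_t t\,\Delta t\,p_t}, plus \eqn{\Delta t / 2} when
#' `corrected` — the deterministic value the Monte-Carlo mean of corrected
#' draws converges to. With residual mass the unconditional mean is undefined
#' (some draws never happen); `conditional = TRUE` instead returns the mean
#' given that the event occurs by the horizon.
#'
#' @param pmf an [event_pmf()].
#' @param corrected include the \eqn{\Delta t / 2} continuous-time shift?
#' @param conditional condition on the event occurring by the horizon.
#' @return Expected time, in the grid's time units.
#' @export
expected_time <- function(pmf, corrected = TRUE, conditional = FALSE) {
  stopifnot(inherits(pmf, "event_pmf"))
  if (pmf$residual > 1e-12 && !conditional)
    stop("pmf has residual beyond-horizon mass ",
         format(pmf$residual, digits = 3),
         "; use conditional = TRUE for the mean given the event occurs",
         call. = FALSE)
  tt <- pmf$origin + pmf$delta_t * (seq_along(pmf$probs) - 1L)
  m <- sum(tt * pmf$probs) / sum(pmf$probs)
  if (corrected) m + pmf$delta_t / 2 else m
}
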