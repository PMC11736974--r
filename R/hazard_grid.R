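#' Uniform grid of piecewise-constant hazards
#'
#' A `hazard_grid` holds per-interval hazards \eqn{h_t} on a uniform time grid:
#' interval \eqn{t} covers \eqn{[t \Delta t, (t+1)\Delta t)} (shifted by
#' `origin`), \eqn{t = 0, \dots, Z}, and the hazard is assumed constant within
#' each interval. This is the native representation of the nonparametric
#' sampling method: every other form (cumulative hazard, CDF, interval
#' probabilities) is derived from it, and covariate effects act on it
#' multiplicatively.
#'
#' @param hazards numeric vector of per-interval hazards, all finite and
#'   \eqn{\ge 0}, length \eqn{Z + 1 \ge 1}. Units: events per unit time.
#' @param delta_t interval width \eqn{\Delta t > 0}, in time units.
#' @param origin start time of the first interval (default 0).
#' @return An object of class `"hazard_grid"`.
#' @seealso [cumulative_from_hazards()], [event_pmf_from()], [nps()],
#'   [rescale_hazards()]
#' @examples
#' g <- hazard_grid(rep(0.1, 50), delta_t = 1)
#' head(as.data.frame(g))
#' @export
hazard_grid <- function(hazards, delta_t = 1, origin = 0) {
  hazards <- as.numeric(hazards)
  if (length(hazards) < 1L)
    stop("'hazards' must have length >= 1", call. = FALSE)
  if (anyNA(hazards) || any(!is.finite(hazards)))
    stop("all hazards must be finite", call. = FALSE)
  if (any(hazards < 0))
    stop("all hazards must be >= 0 (first offending index: ",
         which(hazards < 0)[1L], ")", call. = FALSE)
  check_delta_t(delta_t)
  structure(list(hazards = hazards, delta_t = as.numeric(delta_t),
                 origin = as.numeric(origin)),
            class = "hazard_grid")
}

#' Cumulative-hazard grid
#'
#' Values \eqn{H_t} at interval starts \eqn{t = 0, \dots, Z+1}; always one
#' entry more than the hazard grid it derives from, with \eqn{H_0 = 0}.
#'
#' @param values nondecreasing, finite, nonnegative; first value 0.
#' @inheritParams hazard_grid
#' @return An object of class `"cumhaz_grid"`.
#' @export
cumhaz_grid <- function(values, delta_t = 1, origin = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values)))
    stop("cumulative hazard values must be finite", call. = FALSE)
  if (values[1L] != 0)
    stop("cumulative hazard must start at 0", call. = FALSE)
  if (is.unsorted(values))
    stop("cumulative hazard must be nondecreasing", call. = FALSE)
  check_delta_t(delta_t)
  structure(list(values = values, delta_t = as.numeric(delta_t),
                 origin = as.numeric(origin)),
            class = "cumhaz_grid")
}

#' Discrete CDF grid
#'
#' Event-time CDF \eqn{F_t = 1 - \exp(-H_t)} at interval starts.
#'
#' @param values nondecreasing values in \eqn{[0, 1]}.
#' @inheritParams hazard_grid
#' @return An object of class `"cdf_grid"`.
#' @export
cdf_grid <- function(values, delta_t = 1, origin = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values)))
    stop("CDF values must be finite", call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop("CDF values must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(values))
    stop("CDF must be nondecreasing", call. = FALSE)
  check_delta_t(delta_t)
  structure(list(values = values, delta_t = as.numeric(delta_t),
                 origin = as.numeric(origin)),
            class = "cdf_grid")
}

#' Interval-probability mass function of the event time
#'
#' The parameter of the categorical distribution over time intervals:
#' \eqn{p_t = F_{t+1} - F_t} for \eqn{t = 0, \dots, Z}, plus the residual
#' probability that no event has occurred by the grid horizon,
#' \eqn{1 - F_{Z+1}}. The residual is carried explicitly; draws landing in it
#' come back as a beyond-horizon sentinel (`NA` category) unless the pmf is
#' renormalized.
#'
#' @param probs numeric vector of interval probabilities, all \eqn{\ge 0}.
#' @param residual probability of no event by the horizon.
#' @inheritParams hazard_grid
#' @return An object of class `"event_pmf"`.
#' @export
event_pmf <- function(probs, delta_t = 1, residual = 0, origin = 0) {
  probs <- as.numeric(probs)
  if (length(probs) < 1L || anyNA(probs) || any(!is.finite(probs)))
    stop("probabilities must be finite", call. = FALSE)
  if (any(probs < 0))
    stop("probabilities must be >= 0", call. = FALSE)
  if (!is.finite(residual) || residual < 0)
    stop("'residual' must be finite and >= 0", call. = FALSE)
  tot <- sum(probs) + residual
  if (abs(tot - 1) > 1e-9)
    stop(sprintf("probabilities + residual must sum to 1 (got %.12g)", tot),
         call. = FALSE)
  check_delta_t(delta_t)
  structure(list(probs = probs, delta_t = as.numeric(delta_t),
                 residual = as.numeric(residual), origin = as.numeric(origin)),
            class = "event_pmf")
}

check_delta_t <- function(delta_t) {
  if (!is.numeric(delta_t) || length(delta_t) != 1L || !is.finite(delta_t) ||
      delta_t <= 0)
    stop("'delta_t' must be a single positive number", call. = FALSE)
  invisible(delta_t)
}

#' Accumulate interval hazards into a cumulative-hazard grid
#'
#' Computes \eqn{H_t = \sum_{x < t} h_x \Delta t} at every interval start, so
#' that a constant hazard \eqn{\lambda} gives \eqn{H(t) = \lambda t}
#' regardless of the grid resolution. The output has one more entry than the
#' input and starts at 0.
#'
#' @param grid a [hazard_grid()].
#' @return A [cumhaz_grid()].
#' @examples
#' cumulative_from_hazards(hazard_grid(c(0.2, 0.4), delta_t = 0.5))$values
#' # 0.0 0.1 0.3
#' @export
cumulative_from_hazards <- function(grid) {
  stopifnot(inherits(grid, "hazard_grid"))
  cumhaz_grid(c(0, cumsum(grid$hazards) * grid$delta_t),
              delta_t = grid$delta_t, origin = grid$origin)
}

#' CDF grid from a cumulative-hazard grid
#'
#' \eqn{F_t = 1 - \exp(-H_t)} pointwise.
#'
#' @param cum a [cumhaz_grid()].
#' @return A [cdf_grid()].
#' @export
cdf_from_cumulative <- function(cum) {
  stopifnot(inherits(cum, "cumhaz_grid"))
  cdf_grid(-expm1(-cum$values), delta_t = cum$delta_t, origin = cum$origin)
}

#' Interval probabilities from a CDF grid
#'
#' \eqn{p_t = F_{t+1} - F_t} for every interval the grid covers; the mass
#' beyond the last tabulated point, \eqn{1 - F_{Z+1}}, becomes the explicit
#' residual. Differences more negative than `-1e-12` are an error; smaller
#' negative round-off is clipped to 0.
#'
#' @param cdf a [cdf_grid()] with at least two values.
#' @return An [event_pmf()].
#' @export
pmf_from_cdf <- function(cdf) {
  stopifnot(inherits(cdf, "cdf_grid"))
  if (length(cdf$values) < 2L)
    stop("need a CDF at >= 2 grid points to form interval probabilities",
         call. = FALSE)
  p <- diff(cdf$values)
  if (any(p < -1e-12))
    stop("CDF decreases beyond tolerance", call. = FALSE)
  p[p < 0] <- 0
  res <- max(0, 1 - cdf$values[length(cdf$values)])
  # remove round-off so probs + residual sum to 1 exactly at machine precision
  tot <- sum(p) + res
  event_pmf(p / tot, delta_t = cdf$delta_t, residual = res / tot,
            origin = cdf$origin)
}

#' Discretize a continuous cumulative hazard into interval hazards
#'
#' Finite differences of \eqn{H} on the uniform grid:
#' \eqn{h_t = (H((t+1)\Delta t) - H(t \Delta t)) / \Delta t}, so that
#' re-accumulating the grid reproduces \eqn{H} at the grid points exactly.
#' This is the interval-averaged (exact) discretization.
#'
#' @param H vectorized nondecreasing function of time, \eqn{H(0) = 0} assumed
#'   only up to an additive constant (differences are used).
#' @param delta_t interval width.
#' @param horizon end of the grid; the last interval starts at
#'   `horizon - delta_t`.
#' @param origin start time.
#' @return A [hazard_grid()].
#' @export
hazards_from_cumulative_function <- function(H, delta_t, horizon, origin = 0) {
  check_delta_t(delta_t)
  nint <- floor(horizon / delta_t + 1e-9)
  if (nint < 1L) stop("'horizon' must cover at least one interval",
                      call. = FALSE)
  tpts <- origin + delta_t * (0:nint)
  vals <- H(tpts)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("cumulative hazard function returned non-finite values",
         call. = FALSE)
  d <- diff(vals)
  if (any(d < -1e-12))
    stop("cumulative hazard function is decreasing", call. = FALSE)
  d[d < 0] <- 0
  hazard_grid(d / delta_t, delta_t = delta_t, origin = origin)
}

#' Integrate a continuous hazard function onto a cumulative-hazard grid
#'
#' \eqn{H(t) = \int_0^t h(x)\,dx} at every grid point, by adaptive quadrature
#' on each interval (so accuracy does not degrade with grid length).
#'
#' @param h nonnegative integrable hazard function of time.
#' @param delta_t interval width.
#' @param horizon end of the grid span.
#' @param origin start time.
#' @param rel.tol quadrature relative tolerance per interval.
#' @return A [cumhaz_grid()].
#' @export
cumulative_from_hazard_function <- function(h, delta_t, horizon, origin = 0,
                                            rel.tol = 1e-10) {
  check_delta_t(delta_t)
  nint <- floor(horizon / delta_t + 1e-9)
  if (nint < 1L) stop("'horizon' must cover at least one interval",
                      call. = FALSE)
  tpts <- origin + delta_t * (0:nint)
  probe <- h(tpts)
  if (anyNA(probe) || any(!is.finite(probe)) || any(probe < 0))
    stop("hazard function must be finite and >= 0 on the grid", call. = FALSE)
  inc <- vapply(seq_len(nint), function(i) {
    stats::integrate(h, tpts[i], tpts[i + 1L], rel.tol = rel.tol,
                     stop.on.error = TRUE)$value
  }, numeric(1))
  if (any(inc < -1e-12))
    stop("hazard function integrates to a negative increment", call. = FALSE)
  inc[inc < 0] <- 0
  cumhaz_grid(c(0, cumsum(inc)), delta_t = delta_t, origin = origin)
}

#' Rescale a hazard grid to another time scale
#'
#' Multiplies every interval hazard by `scale_ratio` and divides the interval
#' width by the same ratio, e.g. `scale_ratio = 1/12` turns yearly hazards
#' into monthly ones. The cumulative hazard over any fixed physical span is
#' unchanged.
#'
#' @param grid a [hazard_grid()].
#' @param scale_ratio positive ratio of the given time scale to the target
#'   scale.
#' @return A [hazard_grid()] on the target scale.
#' @examples
#' rescale_hazards(hazard_grid(0.12), 1 / 12)$hazards  # 0.01
#' @export
rescale_hazards <- function(grid, scale_ratio) {
  stopifnot(inherits(grid, "hazard_grid"))
  if (!is.numeric(scale_ratio) || length(scale_ratio) != 1L ||
      !is.finite(scale_ratio) || scale_ratio <= 0)
    stop("'scale_ratio' must be a single positive number", call. = FALSE)
  hazard_grid(grid$hazards * scale_ratio,
              delta_t = grid$delta_t / scale_ratio,
              origin = grid$origin / scale_ratio)
}

#' @rdname event_pmf
#' @details `event_pmf_from()` runs the full conversion chain from any earlier
#'   representation (interval hazards, cumulative hazards, or a CDF grid) down
#'   to interval probabilities.
#' @param x a [hazard_grid()], [cumhaz_grid()] or [cdf_grid()].
#' @export
event_pmf_from <- function(x) {
  if (inherits(x, "hazard_grid")) x <- cumulative_from_hazards(x)
  if (inherits(x, "cumhaz_grid")) x <- cdf_from_cumulative(x)
  if (inherits(x, "cdf_grid")) return(pmf_from_cdf(x))
  if (inherits(x, "event_pmf")) return(x)
  stop("cannot convert an object of class '", class(x)[1L],
       "' to interval probabilities", call. = FALSE)
}

# ---- data-frame views and CSV round trip --------------------------------

#' @export
as.data.frame.hazard_grid <- function(x, ...) {
  t0 <- x$origin + x$delta_t * (seq_along(x$hazards) - 1L)
  data.frame(t_start = t0, delta_t = x$delta_t, hazard = x$hazards)
}

#' @export
as.data.frame.cumhaz_grid <- function(x, ...) {
  t0 <- x$origin + x$delta_t * (seq_along(x$values) - 1L)
  data.frame(t_start = t0, delta_t = x$delta_t, cumulative_hazard = x$values)
}

#' @export
as.data.frame.cdf_grid <- function(x, ...) {
  t0 <- x$origin + x$delta_t * (seq_along(x$values) - 1L)
  data.frame(t_start = t0, delta_t = x$delta_t, cdf = x$values)
}

#' @export
as.data.frame.event_pmf <- function(x, ...) {
  t0 <- x$origin + x$delta_t * (seq_along(x$probs) - 1L)
  data.frame(t_start = t0, delta_t = x$delta_t, probability = x$probs)
}

#' Read or write a hazard grid as CSV
#'
#' The on-disk format is a headered CSV with columns `t_start`, `delta_t`,
#' `hazard` ('.' decimal separator, UTF-8). `t_start` must advance by the
#' single shared `delta_t`.
#'
#' @param file path to a CSV file.
#' @return `read_hazard_grid()` returns a [hazard_grid()];
#'   `write_hazard_grid()` returns `file` invisibly.
#' @export
read_hazard_grid <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("t_start", "delta_t", "hazard")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("hazard CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- unique(d$delta_t)
  if (length(dt) != 1L)
    stop("hazard CSV must use a single delta_t", call. = FALSE)
  d <- d[order(d$t_start), , drop = FALSE]
  if (nrow(d) > 1L &&
      any(abs(diff(d$t_start) - dt) > 1e-9 * max(1, abs(dt))))
    stop("t_start must advance uniformly by delta_t", call. = FALSE)
  hazard_grid(d$hazard, delta_t = dt, origin = d$t_start[1L])
}

#' @rdname read_hazard_grid
#' @param grid a [hazard_grid()].
#' @export
write_hazard_grid <- function(grid, file) {
  stopifnot(inherits(grid, "hazard_grid"))
  utils::write.csv(as.data.frame(grid), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.hazard_grid <- function(x, ...) {
  cat(sprintf("Hazard grid: %d intervals of width %g starting at %g\n",
              length(x$hazards), x$delta_t, x$origin))
  cat(sprintf("  hazards in [%g, %g], total cumulative hazard %g\n",
              min(x$hazards), max(x$hazards),
              sum(x$hazards) * x$delta_t))
  invisible(x)
}

#' @export
print.event_pmf <- function(x, ...) {
  cat(sprintf(
    "Event-interval pmf: %d intervals of width %g, residual mass %.3g\n",
    length(x$probs), x$delta_t, x$residual))
  invisible(x)
}
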