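#' Discretize a hazard into a sampleable event-time distribution
#'
#' @description
#' `nps()` is the package's front door: it takes a hazard in any supported
#' form — a parametric [dist_spec()], a continuous hazard function, a
#' [hazard_grid()], cumulative-hazard or CDF grid, an [event_pmf()], or a
#' [life_table()] — and returns a fitted `"nps"` object holding the
#' categorical distribution over time intervals that the nonparametric
#' sampling method draws from. Draw from it with [simulate()], read its exact
#' expectation with [mean()], and inspect it with `print()`, `summary()` and
#' `plot()`.
#'
#' @details
#' Two discretization routes are available for continuous inputs:
#' \describe{
#'   \item{`method = "average"`}{interval-averaged hazards from exact finite
#'     differences of the cumulative hazard,
#'     \eqn{h_t = (H((t+1)\Delta t) - H(t\Delta t))/\Delta t}; the interval
#'     probabilities then reproduce the continuous distribution exactly at
#'     the grid points. The default.}
#'   \item{`method = "left"`}{the hazard evaluated at each interval's left
#'     endpoint, \eqn{h_t = h(t \Delta t)}; this is the natural route when
#'     the hazard is only known pointwise — e.g. driven by a covariate path
#'     tabulated at interval starts — and carries the discretization bias of
#'     freezing the hazard at the interval start.}
#' }
#' When `horizon` is omitted it is grown automatically until the survival
#' beyond it falls below `residual_tol`. Remaining beyond-horizon mass is
#' kept as an explicit residual category unless `renormalize = TRUE`, which
#' folds it back into the interval probabilities (conditioning on the event
#' occurring by the horizon).
#'
#' @param x the hazard, in any of the supported forms.
#' @param ... passed between methods.
#' @param delta_t interval width of the discretization grid.
#' @param horizon end of the grid; `NULL` (default) chooses it automatically
#'   for continuous inputs.
#' @param method discretization route for continuous inputs (see Details).
#' @param renormalize fold residual beyond-horizon mass into the interval
#'   probabilities?
#' @param residual_tol survival level that the automatic horizon must reach.
#' @return An object of class `"nps"` with components `pmf` (the
#'   [event_pmf()]) and `source` (a short description of the input).
#' @examples
#' m <- nps(dist_spec("exponential", rate = 0.1), delta_t = 1)
#' mean(m)                      # exact corrected expectation, ~10
#' tt <- simulate(m, 1e4, seed = 1)
#' mean(tt)
#' @export
nps <- function(x, ...) UseMethod("nps")

#' @rdname nps
#' @export
nps.dist_spec <- function(x, delta_t = 1, horizon = NULL,
                          method = c("average", "left"),
                          renormalize = FALSE, residual_tol = 1e-9, ...) {
  method <- match.arg(method)
  H <- cumulative_hazard_function(x)
  if (is.null(horizon))
    horizon <- auto_horizon(H, delta_t, residual_tol)
  grid <- if (method == "average")
    hazards_from_cumulative_function(H, delta_t, horizon)
  else {
    h <- hazard_function(x)
    nint <- floor(horizon / delta_t + 1e-9)
    hazard_grid(h(delta_t * (0:(nint - 1L))), delta_t = delta_t)
  }
  new_nps(grid, paste(x$family, "baseline"), renormalize)
}

#' @rdname nps
#' @param is_cumulative for function input: is `x` the cumulative hazard
#'   \eqn{H(t)} rather than the hazard \eqn{h(t)}?
#' @export
nps.function <- function(x, delta_t = 1, horizon = NULL,
                         method = c("average", "left"),
                         renormalize = FALSE, residual_tol = 1e-9,
                         is_cumulative = FALSE, ...) {
  method <- match.arg(method)
  if (is_cumulative) {
    if (is.null(horizon))
      horizon <- auto_horizon(x, delta_t, residual_tol)
    grid <- hazards_from_cumulative_function(x, delta_t, horizon)
    return(new_nps(grid, "cumulative hazard function", renormalize))
  }
  Hq <- function(t) vapply(t, function(u)
    if (u == 0) 0 else
      stats::integrate(x, 0, u, rel.tol = 1e-10,
                       stop.on.error = TRUE)$value, numeric(1))
  if (is.null(horizon))
    horizon <- auto_horizon(Hq, delta_t, residual_tol)
  grid <- if (method == "average") {
    cum <- cumulative_from_hazard_function(x, delta_t, horizon)
    hazard_grid(diff(cum$values) / delta_t, delta_t = delta_t)
  } else {
    nint <- floor(horizon / delta_t + 1e-9)
    hazard_grid(x(delta_t * (0:(nint - 1L))), delta_t = delta_t)
  }
  new_nps(grid, "hazard function", renormalize)
}

#' @rdname nps
#' @export
nps.hazard_grid <- function(x, renormalize = FALSE, ...) {
  new_nps(x, "hazard grid", renormalize)
}

#' @rdname nps
#' @export
nps.cumhaz_grid <- function(x, renormalize = FALSE, ...) {
  new_nps(x, "cumulative-hazard grid", renormalize)
}

#' @rdname nps
#' @export
nps.cdf_grid <- function(x, renormalize = FALSE, ...) {
  new_nps(x, "CDF grid", renormalize)
}

#' @rdname nps
#' @export
nps.event_pmf <- function(x, renormalize = FALSE, ...) {
  new_nps(x, "interval probabilities", renormalize)
}

#' @rdname nps
#' @param terminal_cap_age passed to [hazards_from_life_table()].
#' @export
nps.life_table <- function(x, terminal_cap_age = 110, renormalize = FALSE,
                           ...) {
  grid <- hazards_from_life_table(x, terminal_cap_age)
  src <- if (is.null(x$group)) "life table"
         else paste("life table, group", x$group)
  new_nps(grid, src, renormalize)
}

new_nps <- function(x, source, renormalize) {
  pmf <- event_pmf_from(x)
  if (renormalize && pmf$residual > 0) {
    s <- sum(pmf$probs)
    pmf <- event_pmf(pmf$probs / s, delta_t = pmf$delta_t, residual = 0,
                     origin = pmf$origin)
  }
  structure(list(pmf = pmf, source = source), class = "nps")
}

# smallest power-of-two multiple of delta_t whose survival is < residual_tol
auto_horizon <- function(Hfun, delta_t, residual_tol = 1e-9) {
  target <- -log(residual_tol)
  n <- 1
  while (Hfun(n * delta_t) < target && n < 2^30) n <- n * 2
  if (Hfun(n * delta_t) < target)
    stop("could not reach survival < ", residual_tol,
         " within 2^30 intervals; supply 'horizon' explicitly",
         call. = FALSE)
  n * delta_t
}

#' @export
print.nps <- function(x, ...) {
  cat("Nonparametric event-time sampler (", x$source, ")\n", sep = "")
  cat(sprintf("  %d intervals of width %g; residual beyond-horizon mass %.3g\n",
              length(x$pmf$probs), x$pmf$delta_t, x$pmf$residual))
  invisible(x)
}

#' @export
summary.nps <- function(object, ...) {
  pmf <- object$pmf
  out <- list(
    source = object$source,
    intervals = length(pmf$probs),
    delta_t = pmf$delta_t,
    residual = pmf$residual,
    mean_uncorrected = expected_time(pmf, corrected = FALSE,
                                     conditional = TRUE),
    mean_corrected = expected_time(pmf, corrected = TRUE,
                                   conditional = TRUE))
  class(out) <- "summary.nps"
  out
}

#' @export
print.summary.nps <- function(x, ...) {
  cat("Nonparametric event-time sampler (", x$source, ")\n", sep = "")
  cat(sprintf("  grid: %d intervals of width %g (horizon %g)\n",
              x$intervals, x$delta_t, x$intervals * x$delta_t))
  cat(sprintf("  residual beyond-horizon mass: %.3g\n", x$residual))
  cat(sprintf("  expected event time: %.4f uncorrected, %.4f corrected%s\n",
              x$mean_uncorrected, x$mean_corrected,
              if (x$residual > 1e-12) " (conditional on event)" else ""))
  invisible(x)
}

#' @rdname nps
#' @param corrected,conditional see [expected_time()].
#' @export
mean.nps <- function(x, corrected = TRUE, conditional = x$pmf$residual > 0,
                     ...) {
  expected_time(x$pmf, corrected = corrected, conditional = conditional)
}

#' Draw event times from a fitted sampler
#'
#' Samples `nsim` interval categories from the discretized distribution and,
#' unless `correct = FALSE`, applies the uniform continuous-time correction.
#'
#' @param object an `"nps"` object.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param correct apply the \eqn{U[0, \Delta t)} continuous-time correction?
#' @param ... unused.
#' @return An [event_times] object.
#' @export
simulate.nps <- function(object, nsim = 1, seed = NULL, correct = TRUE,
                         ...) {
  set_local_seed(seed)
  draws <- sample_univariate(object$pmf, nsim)
  if (correct) continuous_time_correction(draws) else draws
}

#' @export
plot.nps <- function(x, ...) {
  pmf <- x$pmf
  tt <- pmf$origin + pmf$delta_t * (seq_along(pmf$probs) - 1L)
  graphics::plot(tt, pmf$probs, type = "h", xlab = "time",
                 ylab = "interval probability",
                 main = paste("Event-interval pmf:", x$source), ...)
  invisible(x)
}
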