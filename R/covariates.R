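#' Proportional-hazards covariate effect
#'
#' @description
#' Specifies how a covariate multiplies a baseline hazard. With
#' `interpretation = "log_hazard_ratio"` the per-interval multiplier is
#' \eqn{e^{\beta x}} (the usual Cox-model coding, \eqn{\beta} the log-hazard
#' ratio); with `"hazard_ratio"` the coefficient is itself the per-unit
#' multiplier, \eqn{\beta^x}, which requires \eqn{\beta > 0}.
#'
#' @param beta covariate coefficient.
#' @param interpretation `"log_hazard_ratio"` (default) or `"hazard_ratio"`.
#' @return An object of class `"effect_spec"`.
#' @export
effect_spec <- function(beta,
                        interpretation = c("log_hazard_ratio",
                                           "hazard_ratio")) {
  interpretation <- match.arg(interpretation)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta))
    stop("'beta' must be a single finite number", call. = FALSE)
  if (interpretation == "hazard_ratio" && beta <= 0)
    stop("a hazard ratio must be > 0", call. = FALSE)
  structure(list(beta = beta, interpretation = interpretation),
            class = "effect_spec")
}

# per-unit multiplier m so the hazard scales by m^x
effect_multiplier <- function(effect) {
  stopifnot(inherits(effect, "effect_spec"))
  if (effect$interpretation == "log_hazard_ratio") exp(effect$beta)
  else effect$beta
}

#' Per-individual covariate path on the hazard grid
#'
#' Covariate values \eqn{x_i(t)} tabulated at the interval starts of the
#' hazard grid they will scale; the covariate is treated as constant within
#' each interval.
#'
#' @param values finite numeric vector, one value per grid interval.
#' @param delta_t interval width of the matching grid.
#' @param id optional individual label.
#' @return An object of class `"covariate_path"`.
#' @export
covariate_path <- function(values, delta_t = 1, id = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values)))
    stop("covariate values must be finite", call. = FALSE)
  check_delta_t(delta_t)
  structure(list(values = values, delta_t = as.numeric(delta_t), id = id),
            class = "covariate_path")
}

#' Scale a baseline hazard by a time-independent covariate
#'
#' \eqn{h_{i,t} = h_{0,t} \, m^{x}} for every interval, where \eqn{m} is the
#' per-unit multiplier implied by `effect`.
#'
#' @param h0 baseline [hazard_grid()].
#' @param x scalar covariate value for the individual.
#' @param effect an [effect_spec()].
#' @return A [hazard_grid()] for the individual.
#' @examples
#' h0 <- hazard_grid(rep(0.1, 100))
#' ph_constant_covariate(h0, 1, effect_spec(log(2)))$hazards[1]  # 0.2
#' @export
ph_constant_covariate <- function(h0, x, effect) {
  stopifnot(inherits(h0, "hazard_grid"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'x' must be a single finite covariate value", call. = FALSE)
  mult <- effect_multiplier(effect)^x
  if (!is.finite(mult))
    stop("covariate effect produces a non-finite hazard multiplier",
         call. = FALSE)
  hazard_grid(h0$hazards * mult, delta_t = h0$delta_t, origin = h0$origin)
}

#' Scale a baseline hazard by a time-dependent covariate path
#'
#' \eqn{h_{i,t} = h_{0,t} \, m^{x_i(t)}} interval by interval, with the
#' covariate held at its interval-start value within each interval.
#'
#' @param h0 baseline [hazard_grid()].
#' @param path a [covariate_path()] or numeric vector, length matching `h0`.
#' @param effect an [effect_spec()].
#' @return A [hazard_grid()] for the individual.
#' @export
ph_time_dependent <- function(h0, path, effect) {
  stopifnot(inherits(h0, "hazard_grid"))
  vals <- if (inherits(path, "covariate_path")) path$values
          else as.numeric(path)
  if (length(vals) != length(h0$hazards))
    stop("covariate path length (", length(vals),
         ") must match the hazard grid (", length(h0$hazards), ")",
         call. = FALSE)
  mult <- effect_multiplier(effect)^vals
  if (any(!is.finite(mult)))
    stop("covariate effect produces non-finite hazard multipliers",
         call. = FALSE)
  hazard_grid(h0$hazards * mult, delta_t = h0$delta_t, origin = h0$origin)
}

#' Gaussian random-walk covariate paths
#'
#' Simulates \eqn{y_i(t) = y_i(t-1) + \epsilon_i}, \eqn{\epsilon_i \sim
#' N(0, \sigma)}, one path per individual, tabulated at `horizon` interval
#' starts (the first value is `init`, the walk's state at time 0).
#'
#' @param n_paths number of independent paths.
#' @param horizon number of grid intervals (path length).
#' @param sigma innovation standard deviation, \eqn{\ge 0}.
#' @param init common starting value \eqn{y_i(0)} (default 0).
#' @param delta_t interval width of the target grid.
#' @param seed optional integer seed.
#' @return A numeric matrix with `n_paths` rows and `horizon` columns, class
#'   `"covariate_paths"`; row `k` is individual `k`'s path.
#' @export
gaussian_random_walk <- function(n_paths, horizon, sigma, init = 0,
                                 delta_t = 1, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("'sigma' must be a single number >= 0", call. = FALSE)
  if (horizon < 1L) stop("'horizon' must be >= 1", call. = FALSE)
  if (n_paths < 1L) stop("'n_paths' must be >= 1", call. = FALSE)
  set_local_seed(seed)
  steps <- matrix(stats::rnorm(n_paths * (horizon - 1L), 0, sigma),
                  nrow = n_paths)
  paths <- cbind(rep(init, n_paths),
                 if (horizon > 1L) init + rowCumsums(steps))
  check_delta_t(delta_t)
  structure(paths, class = c("covariate_paths", class(paths)),
            delta_t = delta_t)
}

rowCumsums <- function(m) {
  if (ncol(m) > 1L)
    for (j in seq_len(ncol(m))[-1L]) m[, j] <- m[, j] + m[, j - 1L]
  m
}

#' Individual-specific probability matrix from covariate paths
#'
#' Applies [ph_time_dependent()] to every path, runs the full hazard-to-pmf
#' conversion per individual, and stacks the resulting interval probabilities
#' into a [probability_matrix()] ready for [sample_multivariate()].
#'
#' @param h0 baseline [hazard_grid()].
#' @param paths a `"covariate_paths"` matrix (paths in rows), a list of
#'   [covariate_path()] objects, or a plain numeric matrix.
#' @param effect an [effect_spec()].
#' @return A [probability_matrix()] with one row per path.
#' @export
probability_matrix_from_paths <- function(h0, paths, effect) {
  stopifnot(inherits(h0, "hazard_grid"))
  if (is.list(paths) && !is.matrix(paths))
    paths <- do.call(rbind, lapply(paths, function(p) {
      if (inherits(p, "covariate_path")) p$values else as.numeric(p)
    }))
  paths <- unclass(as.matrix(paths))
  if (ncol(paths) != length(h0$hazards))
    stop("each path must have one value per baseline interval", call. = FALSE)
  # vectorized over individuals: H = dt * rowCumsums(h0 * m^x), F = 1-exp(-H)
  mult <- effect_multiplier(effect)^paths
  if (any(!is.finite(mult)))
    stop("covariate effect produces non-finite hazard multipliers",
         call. = FALSE)
  haz <- sweep(mult, 2L, h0$hazards, `*`)
  H <- cbind(0, rowCumsums(haz) * h0$delta_t)
  F <- -expm1(-H)
  p <- F[, -1L, drop = FALSE] - F[, -ncol(F), drop = FALSE]
  p[p < 0] <- 0
  res <- pmax(0, 1 - F[, ncol(F)])
  tot <- rowSums(p) + res
  probability_matrix(p / tot, delta_t = h0$delta_t, residual = res / tot,
                     origin = h0$origin)
}
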