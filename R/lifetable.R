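#' Life table
#'
#' An age-indexed mortality schedule: contiguous integer ages from 0, with
#' either `qx` (conditional probability of dying within the age interval) or
#' `mx` (central death rate), exactly one of the two. The last row is treated
#' as an open age interval.
#'
#' @param ages integer start ages, contiguous from 0 with step 1.
#' @param qx conditional death probabilities in \eqn{[0, 1]}, or `NULL`.
#' @param mx central death rates \eqn{\ge 0}, or `NULL`.
#' @param group optional label (e.g. sex).
#' @return An object of class `"life_table"`.
#' @export
life_table <- function(ages, qx = NULL, mx = NULL, group = NULL) {
  ages <- as.integer(ages)
  if (is.null(qx) == is.null(mx))
    stop("supply exactly one of 'qx' or 'mx'", call. = FALSE)
  if (length(ages) < 1L || ages[1L] != 0L ||
      (length(ages) > 1L && any(diff(ages) != 1L)))
    stop("ages must be contiguous integers starting at 0", call. = FALSE)
  rates <- if (is.null(qx)) mx else qx
  if (length(rates) != length(ages))
    stop("mortality column length must match 'ages'", call. = FALSE)
  if (anyNA(rates) || any(!is.finite(rates)))
    stop("mortality values must be finite", call. = FALSE)
  if (!is.null(qx)) {
    bad <- which(qx < 0 | qx > 1)
    if (length(bad))
      stop("qx outside [0, 1] at age ", ages[bad[1L]], " (row ", bad[1L],
           ")", call. = FALSE)
  } else if (any(mx < 0)) {
    stop("mx must be >= 0 (age ", ages[which(mx < 0)[1L]], ")",
         call. = FALSE)
  }
  structure(list(ages = ages, qx = qx, mx = mx, group = group),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages 0-%d (%s)%s\n", max(x$ages),
              if (is.null(x$qx)) "mx" else "qx",
              if (is.null(x$group)) "" else paste0(", group ", x$group)))
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  d <- data.frame(age = x$ages)
  if (!is.null(x$qx)) d$qx <- x$qx else d$mx <- x$mx
  if (!is.null(x$group)) d$group <- x$group
  d
}

#' Read life tables from CSV
#'
#' Expects a header with an `age` column plus `qx` or `mx`; an optional
#' `group` column splits the file into one table per group.
#'
#' @param file path to a CSV file.
#' @return A [life_table()], or a named list of them when `group` is present
#'   with more than one level.
#' @export
read_life_table <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"age" %in% names(d))
    stop("life-table CSV must have an 'age' column", call. = FALSE)
  has_q <- "qx" %in% names(d); has_m <- "mx" %in% names(d)
  if (!has_q && !has_m)
    stop("life-table CSV must have a 'qx' or 'mx' column", call. = FALSE)
  build <- function(dd, grp) {
    dd <- dd[order(dd$age), , drop = FALSE]
    life_table(dd$age,
               qx = if (has_q) dd$qx,
               mx = if (!has_q && has_m) dd$mx,
               group = grp)
  }
  if ("group" %in% names(d) && length(unique(d$group)) > 1L) {
    grps <- unique(d$group)
    out <- lapply(grps, function(g) build(d[d$group == g, , drop = FALSE], g))
    names(out) <- grps
    out
  } else {
    build(d, if ("group" %in% names(d)) d$group[1L] else NULL)
  }
}

#' Convert a life table to a hazard grid
#'
#' Per-age hazards under the within-interval constant-hazard assumption:
#' \eqn{h_x = -\log(1 - q_x)} when `qx` is given (exact inverse of
#' \eqn{q_x = 1 - e^{-h_x}}), or \eqn{h_x = m_x} when `mx` is given. Ages
#' beyond the table's last closed interval are filled with the terminal
#' hazard up to `terminal_cap_age`, so the open interval does not collapse
#' into a single spiked category.
#'
#' @param lt a [life_table()].
#' @param terminal_cap_age age at which the extended grid stops (default
#'   110); the residual mass beyond it should be negligible for realistic
#'   schedules.
#' @return A [hazard_grid()] with `delta_t = 1` (years of age).
#' @export
hazards_from_life_table <- function(lt, terminal_cap_age = 110) {
  stopifnot(inherits(lt, "life_table"))
  if (!is.null(lt$qx)) {
    closed <- lt$qx[-length(lt$qx)]
    if (any(closed >= 1))
      stop("qx = 1 before the terminal age gives an infinite hazard (age ",
           lt$ages[which(closed >= 1)[1L]], ")", call. = FALSE)
    h <- -log1p(-lt$qx)
    if (!is.finite(h[length(h)]))      # terminal qx = 1: reuse previous level
      h[length(h)] <- h[length(h) - 1L]
  } else {
    h <- lt$mx
  }
  n_extra <- max(0L, as.integer(terminal_cap_age) - max(lt$ages) - 1L)
  hazard_grid(c(h, rep(h[length(h)], n_extra)), delta_t = 1)
}

#' Synthetic life table from a mortality law
#'
#' Builds an exact life table from a continuous mortality hazard:
#' \eqn{q_x = 1 - \exp(-\int_x^{x+1} h(u)\,du)}. The law is either a
#' [dist_spec()] or a Gompertz-Makeham specification
#' \eqn{h(u) = a e^{b u} + c} given as `list(a =, b =, c =)`. Deterministic
#' given its parameters; `hazard_scale` rescales the whole schedule, which is
#' how grouped (e.g. sex-specific) fixtures are made.
#'
#' @param law a [dist_spec()] or `list(a, b, c)` of Gompertz-Makeham
#'   parameters.
#' @param max_age last (open) age of the table.
#' @param hazard_scale positive multiplier on the law's hazard.
#' @param group optional label.
#' @return A [life_table()] with `qx`.
#' @examples
#' lt <- synthetic_life_table(list(a = 1e-4, b = 0.09, c = 2e-4))
#' head(as.data.frame(lt))
#' @export
synthetic_life_table <- function(law, max_age = 100, hazard_scale = 1,
                                 group = NULL) {
  if (!is.numeric(hazard_scale) || hazard_scale <= 0)
    stop("'hazard_scale' must be > 0", call. = FALSE)
  Hfun <- synthetic_law_cumulative(law)
  ages <- 0:max_age
  Hv <- hazard_scale * Hfun(c(ages, max_age + 1L))
  qx <- -expm1(-diff(Hv))
  life_table(ages, qx = qx, group = group)
}

# continuous cumulative hazard of a synthetic mortality law
synthetic_law_cumulative <- function(law) {
  if (inherits(law, "dist_spec")) return(cumulative_hazard_function(law))
  if (is.list(law) && all(c("a", "b", "c") %in% names(law))) {
    a <- law$a; b <- law$b; cc <- law$c
    if (a < 0 || b <= 0 || cc < 0)
      stop("Gompertz-Makeham law needs a >= 0, b > 0, c >= 0", call. = FALSE)
    return(function(t) a * expm1(b * t) / b + cc * t)
  }
  stop("'law' must be a dist_spec or list(a =, b =, c =)", call. = FALSE)
}

# continuous hazard of a synthetic mortality law (oracle use)
synthetic_law_hazard <- function(law, hazard_scale = 1) {
  if (inherits(law, "dist_spec")) {
    h <- hazard_function(law)
    return(function(t) hazard_scale * h(t))
  }
  if (is.list(law) && all(c("a", "b", "c") %in% names(law)))
    return(function(t) hazard_scale * (law$a * exp(law$b * t) + law$c))
  stop("'law' must be a dist_spec or list(a =, b =, c =)", call. = FALSE)
}
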