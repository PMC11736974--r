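test_that("accumulating interval hazards scales by the interval width", {
  expect_equal(cumulative_from_hazards(hazard_grid(c(0, 0, 0)))$values,
               c(0, 0, 0, 0))
  expect_equal(
    tail(cumulative_from_hazards(hazard_grid(rep(0.1, 10)))$values, 1), 1.0)
  expect_equal(
    cumulative_from_hazards(hazard_grid(c(0.2, 0.4), delta_t = 0.5))$values,
    c(0, 0.1, 0.3))
  g <- random_hazard_grid()
  expect_length(cumulative_from_hazards(g)$values, length(g$hazards) + 1L)
  expect_error(hazard_grid(c(0.1, -0.2)), ">= 0")
  expect_error(hazard_grid(c(0.1, Inf)), "finite")
  expect_error(hazard_grid(numeric(0)), "length")
  expect_error(hazard_grid(0.1, delta_t = 0), "positive")
})

test_that("CDF transform is 1 - exp(-H) and rejects decreasing input", {
  expect_equal(cdf_from_cumulative(cumhaz_grid(0))$values, 0)
  expect_equal(cdf_from_cumulative(cumhaz_grid(c(0, log(2))))$values,
               c(0, 0.5))
  expect_equal(cdf_from_cumulative(cumhaz_grid(c(0, 1)))$values,
               c(0, 1 - exp(-1)))
  expect_error(cumhaz_grid(c(0, 0.5, 0.4)), "nondecreasing")
  expect_error(cumhaz_grid(c(0.1, 0.2)), "start at 0")
})

test_that("monotone cumulative hazards give monotone CDFs", {
  for (i in 1:20) {
    H1 <- cumsum(c(0, stats::rexp(20)))
    H2 <- H1 + cumsum(c(0, stats::rexp(20, 5)))
    F1 <- cdf_from_cumulative(cumhaz_grid(H1))$values
    F2 <- cdf_from_cumulative(cumhaz_grid(H2))$values
    expect_true(all(F2 >= F1))
  }
})

test_that("finite differences of a continuous cumulative hazard invert the accumulation", {
  g <- hazards_from_cumulative_function(function(t) 0.1 * t, 1, 20)
  expect_equal(g$hazards, rep(0.1, 20))
  g2 <- hazards_from_cumulative_function(function(t) 0.01 * t^2, 1, 10)
  expect_equal(g2$hazards[1:2], c(0.01, 0.03))
  # per-unit-time scale is preserved on a finer grid
  g3 <- hazards_from_cumulative_function(function(t) 0.1 * t, 1 / 12, 2)
  expect_equal(g3$hazards, rep(0.1, 24))
  expect_error(hazards_from_cumulative_function(function(t) -t, 1, 5),
               "decreasing")
  # round trip: re-accumulation reproduces H at the grid points
  H <- function(t) 0.3 * t + 0.004 * t^2 + 0.05 * log1p(t)
  gg <- hazards_from_cumulative_function(H, 0.5, 30)
  back <- cumulative_from_hazards(gg)$values
  expect_equal(back, H(seq(0, 30, by = 0.5)) - H(0), tolerance = 1e-10)
})

test_that("quadrature of a hazard function reproduces closed-form cumulative hazards", {
  cum <- cumulative_from_hazard_function(function(t) rep(0.2, length(t)),
                                         1, 10)
  expect_equal(cum$values, 0.2 * (0:10), tolerance = 1e-10)
  cum2 <- cumulative_from_hazard_function(function(t) 0.02 * t, 1, 10)
  expect_equal(cum2$values[11], 1.0, tolerance = 1e-9)
  cum3 <- cumulative_from_hazard_function(function(t) 0.001 * exp(0.1 * t),
                                          1, 10)
  expect_equal(cum3$values[11], 0.001 * expm1(1) / 0.1, tolerance = 1e-9)
  expect_error(cumulative_from_hazard_function(function(t) t - 1, 1, 5),
               ">= 0")
})

test_that("interval probabilities difference the CDF and carry the residual", {
  p1 <- pmf_from_cdf(cdf_grid(c(0, 0.5, 1)))
  expect_equal(p1$probs, c(0.5, 0.5))
  expect_equal(p1$residual, 0)
  p2 <- pmf_from_cdf(cdf_grid(c(0, 0.3)))
  expect_equal(p2$probs, 0.3)
  expect_equal(p2$residual, 0.7)
  p3 <- exponential_pmf(0.1)
  expect_equal(p3$probs[1], 1 - exp(-0.1), tolerance = 1e-12)
  expect_error(cdf_grid(c(0, 0.5, 0.4)), "nondecreasing")
})

test_that("constant hazards give the geometric interval distribution exactly", {
  for (par in list(c(0.1, 1), c(0.02, 0.5), c(1.5, 0.25))) {
    lam <- par[1]; dt <- par[2]
    pmf <- exponential_pmf(lam, delta_t = dt, n_int = 100)
    t_idx <- 0:99
    expect_equal(pmf$probs,
                 exp(-lam * dt * t_idx) * (1 - exp(-lam * dt)),
                 tolerance = 1e-12)
  }
})

test_that("probabilities plus residual normalize to 1 across random grids", {
  set.seed(11)
  worst <- 0
  for (i in 1:300) {
    pmf <- event_pmf_from(random_hazard_grid())
    worst <- max(worst, abs(sum(pmf$probs) + pmf$residual - 1))
  }
  expect_lt(worst, 1e-12)
})

test_that("rescaling changes the time scale but not the cumulative hazard", {
  expect_equal(rescale_hazards(hazard_grid(0.12), 1 / 12)$hazards, 0.01)
  g <- random_hazard_grid()
  expect_equal(rescale_hazards(g, 1), g)
  back <- rescale_hazards(rescale_hazards(g, 1 / 12), 12)
  expect_equal(back$hazards, g$hazards, tolerance = 1e-12)
  # total cumulative hazard over the same physical span is unchanged
  month <- rescale_hazards(g, 1 / 12)
  expect_equal(sum(month$hazards) * month$delta_t,
               sum(g$hazards) * g$delta_t, tolerance = 1e-12)
  expect_error(rescale_hazards(g, 0), "positive")
})

test_that("hazard grids round-trip through CSV", {
  g <- hazard_grid(c(0.05, 0.1, 0.2), delta_t = 0.5, origin = 2)
  f <- tempfile(fileext = ".csv")
  write_hazard_grid(g, f)
  g2 <- read_hazard_grid(f)
  expect_equal(g2, g)
  # malformed files are named errors
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t_start = 0:2, hazard = 0.1), bad,
                   row.names = FALSE)
  expect_error(read_hazard_grid(bad), "delta_t")
  utils::write.csv(data.frame(t_start = c(0, 1, 3), delta_t = 1,
                              hazard = 0.1), bad, row.names = FALSE)
  expect_error(read_hazard_grid(bad), "uniform")
})
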