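test_that("hazard functions evaluate to their closed forms", {
  expect_equal(hazard_function(dist_spec("exponential", rate = 0.1))(0:5),
               rep(0.1, 6))
  expect_equal(
    hazard_function(dist_spec("weibull_ph", shape = 2, scale = 0.01))(5),
    0.1)
  expect_equal(
    hazard_function(dist_spec("gompertz", shape = 0.1, scale = 0.001))(0),
    0.001)
  expect_error(
    hazard_function(dist_spec("exponential", rate = 0.1))(-1), "t >= 0")
  expect_error(dist_spec("gamma", rate = 0.1), "shape")
  expect_error(dist_spec("lognormal", meanlog = 1, sdlog = -1), "sdlog")
})

test_that("analytic means match their closed forms", {
  expect_equal(analytic_mean(dist_spec("exponential", rate = 0.1)), 10)
  expect_equal(analytic_mean(dist_spec("gamma", rate = 0.1, shape = 4)), 40)
  expect_equal(analytic_mean(dist_spec("lognormal", meanlog = 3.5,
                                       sdlog = 0.15)),
               exp(3.5 + 0.15^2 / 2))
  expect_equal(analytic_mean(dist_spec("weibull_aft", shape = 1.3,
                                       scale = 30.1)),
               30.1 * gamma(1 + 1 / 1.3))
  # weibull PH: E[T] = scale^(-1/shape) Gamma(1 + 1/shape); at shape 2,
  # scale 0.01 this is the Gaussian integral (1/2) sqrt(pi / 0.01)
  expect_equal(analytic_mean(dist_spec("weibull_ph", shape = 2,
                                       scale = 0.01)),
               0.5 * sqrt(pi / 0.01), tolerance = 1e-12)
})

test_that("the survival-integral oracle agrees with analytic means", {
  specs <- list(
    dist_spec("exponential", rate = 0.1),
    dist_spec("gamma", rate = 0.1, shape = 4),
    dist_spec("lognormal", meanlog = 3.5, sdlog = 0.15),
    dist_spec("gompertz", shape = 0.1, scale = 0.001),
    dist_spec("weibull_ph", shape = 2, scale = 0.01),
    dist_spec("weibull_aft", shape = 1.3, scale = 30.1))
  for (spec in specs) {
    expect_equal(numeric_mean_from_hazard(hazard_function(spec)),
                 analytic_mean(spec), tolerance = 1e-4)
  }
  expect_error(
    numeric_mean_from_hazard(function(t) rep(0.01, length(t)), horizon = 10),
    "horizon")
})

test_that("direct sampling agrees with the analytic mean for every family", {
  n <- 1e5
  specs <- list(
    dist_spec("exponential", rate = 0.1),
    dist_spec("gamma", rate = 0.1, shape = 4),
    dist_spec("lognormal", meanlog = 3.5, sdlog = 0.15),
    dist_spec("gompertz", shape = 0.1, scale = 0.001),
    dist_spec("weibull_ph", shape = 2, scale = 0.01),
    dist_spec("weibull_aft", shape = 1.3, scale = 30.1))
  set.seed(19)
  for (spec in specs) {
    x <- direct_sample(spec, n)
    se <- stats::sd(x) / sqrt(n)
    expect_within(mean(x), analytic_mean(spec), 4 * se)
  }
})

test_that("direct sampling under a linear covariate matches the integral oracle", {
  eff <- effect_spec(1.02, "hazard_ratio")
  n <- 2e5
  cases <- list(
    list(spec = dist_spec("exponential", rate = 0.1)),
    list(spec = dist_spec("gompertz", shape = 0.1, scale = 0.001)),
    list(spec = dist_spec("weibull_ph", shape = 2, scale = 0.01)))
  set.seed(23)
  for (cs in cases) {
    hH <- npsamp:::combined_linear_covariate(cs$spec, eff, 0, 1)
    oracle <- numeric_mean_from_hazard(hH$h)
    x <- direct_sample(cs$spec, n, effect = eff, covariate = c(0, 1))
    se <- stats::sd(x) / sqrt(n)
    expect_within(mean(x), oracle, 4 * se)
  }
  expect_error(direct_sample(cases[[1]]$spec, 10, effect = eff), "covariate")
})

test_that("the discretized sampler converges to direct sampling as the grid refines", {
  # deterministic check: the corrected expectation of the left-endpoint
  # discretization approaches the exact mean as delta_t shrinks
  eff <- effect_spec(1.02, "hazard_ratio")
  spec <- dist_spec("exponential", rate = 0.1)
  hH <- npsamp:::combined_linear_covariate(spec, eff, 0, 1)
  exact <- numeric_mean_from_hazard(hH$h)
  gaps <- vapply(c(1, 0.5, 0.1), function(dt) {
    m <- nps(hH$h, delta_t = dt, method = "left")
    abs(expected_time(m$pmf, corrected = TRUE, conditional = TRUE) - exact)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.02)
})

test_that("defective combined hazards are reported, not silently truncated", {
  # a decaying covariate makes the cumulative hazard bounded: some draws
  # never experience the event and inversion must fail loudly
  eff <- effect_spec(0.5, "hazard_ratio")  # multiplier 0.5^t -> bounded H
  spec <- dist_spec("exponential", rate = 0.01)
  expect_error(direct_sample(spec, 1e3, seed = 5, effect = eff,
                             covariate = c(0, 1)),
               "defective|bracket")
})
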