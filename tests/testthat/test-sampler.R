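test_that("degenerate interval probabilities give degenerate draws", {
  pmf <- event_pmf(c(0, 0, 1, 0))
  d <- sample_univariate(pmf, 500, seed = 1)
  expect_true(all(d$categories == 2L))
  dc <- continuous_time_correction(d, seed = 2)
  expect_true(all(dc$times >= 2 & dc$times < 3))
})

test_that("univariate draws follow the interval probabilities", {
  pmf <- event_pmf(c(0.5, 0.5))
  n <- 2e5
  d <- sample_univariate(pmf, n, seed = 42)
  k <- sum(d$categories == 0L)
  expect_within(k, n * 0.5, 4 * sqrt(n * 0.25))
})

test_that("identical seeds reproduce draws in both samplers", {
  pmf <- exponential_pmf(0.1)
  expect_identical(sample_univariate(pmf, 100, seed = 9),
                   sample_univariate(pmf, 100, seed = 9))
  pm <- probability_matrix(matrix(rep(pmf$probs, 50), nrow = 50,
                                  byrow = TRUE),
                           residual = pmf$residual)
  expect_identical(sample_multivariate(pm, seed = 9),
                   sample_multivariate(pm, seed = 9))
  d <- sample_univariate(pmf, 100, seed = 9)
  expect_identical(continuous_time_correction(d, seed = 3),
                   continuous_time_correction(d, seed = 3))
})

test_that("a one-row probability matrix reproduces the univariate sampler", {
  pmf <- exponential_pmf(0.2)
  pm <- probability_matrix(matrix(pmf$probs, nrow = 1),
                           residual = pmf$residual)
  for (s in c(1, 7, 23)) {
    expect_identical(sample_multivariate(pm, seed = s)$categories,
                     sample_univariate(pmf, 1, seed = s)$categories)
  }
})

test_that("multivariate rows are marginally equivalent to univariate draws", {
  pmf <- event_pmf_from(hazard_grid(c(0.3, 0.1, 0.5, 0.2, 0.4)))
  K <- 4e4
  pm <- probability_matrix(matrix(pmf$probs, K, length(pmf$probs),
                                  byrow = TRUE),
                           residual = pmf$residual)
  dm <- sample_multivariate(pm, seed = 5)
  du <- sample_univariate(pmf, K, seed = 17)
  lev <- c(0:(length(pmf$probs) - 1L), NA)
  cm <- table(factor(dm$categories, levels = lev, exclude = NULL))
  cu <- table(factor(du$categories, levels = lev, exclude = NULL))
  p_all <- c(pmf$probs, pmf$residual)
  expect_gt(stats::chisq.test(cm, p = p_all)$p.value, 0.001)
  expect_gt(stats::chisq.test(cu, p = p_all)$p.value, 0.001)
  # and against one another
  expect_gt(stats::chisq.test(rbind(cm, cu))$p.value, 0.001)
})

test_that("heterogeneous rows are sampled from their own distributions", {
  p1 <- exponential_pmf(0.1)
  p2 <- exponential_pmf(0.2, n_int = length(p1$probs))
  n <- 5e4
  pm <- probability_matrix(
    rbind(matrix(p1$probs, n, length(p1$probs), byrow = TRUE),
          matrix(p2$probs, n, length(p2$probs), byrow = TRUE)),
    residual = rep(c(p1$residual, p2$residual), each = n))
  d <- continuous_time_correction(sample_multivariate(pm, seed = 8),
                                  seed = 9)
  m1 <- mean(d$times[1:n], na.rm = TRUE)
  m2 <- mean(d$times[(n + 1):(2 * n)], na.rm = TRUE)
  se <- 10 / sqrt(n)
  expect_within(m1, expected_time(p1, conditional = TRUE), 4 * se)
  expect_within(m2, expected_time(p2, conditional = TRUE), 4 * se)
})

test_that("the uniform correction stays inside each interval and shifts the mean by delta_t/2", {
  pmf <- exponential_pmf(0.3, delta_t = 0.5, n_int = 200)
  d <- sample_univariate(pmf, 1e5, seed = 31)
  dc <- continuous_time_correction(d, seed = 32)
  lo <- d$categories * 0.5
  expect_true(all(dc$times >= lo & dc$times < lo + 0.5, na.rm = TRUE))
  shift <- mean(dc$times - lo, na.rm = TRUE)
  expect_within(shift, 0.25, 4 * 0.5 / sqrt(12 * length(d)))
  expect_error(continuous_time_correction(dc), "already corrected")
})

test_that("expected_time is the deterministic limit of corrected sampling", {
  expect_equal(expected_time(event_pmf(1), corrected = TRUE), 0.5)
  # constant hazard: geometric series in closed form
  pmf <- exponential_pmf(0.1, n_int = 1000)
  q <- exp(-0.1)
  expect_equal(expected_time(pmf, corrected = TRUE, conditional = TRUE),
               q / (1 - q) + 0.5, tolerance = 1e-9)
  # gamma baseline: corrected expectation sits at the analytic mean
  gpmf <- nps(dist_spec("gamma", rate = 0.1, shape = 4))$pmf
  expect_within(expected_time(gpmf, corrected = TRUE, conditional = TRUE),
                40, 0.02)
  expect_error(expected_time(exponential_pmf(0.1, n_int = 10)), "residual")
})

test_that("Monte-Carlo corrected means converge to expected_time", {
  set.seed(77)
  for (i in 1:5) {
    pmf <- event_pmf_from(random_hazard_grid(len = 30, delta_t = 0.5))
    n <- 2e5
    d <- continuous_time_correction(sample_univariate(pmf, n))
    mu <- expected_time(pmf, corrected = TRUE, conditional = TRUE)
    x <- d$times[!is.na(d$times)]
    se <- stats::sd(x) / sqrt(length(x))
    expect_within(mean(x), mu, 4 * se)
  }
})

test_that("beyond-horizon draws propagate as sentinels and are excluded from means", {
  pmf <- event_pmf(c(0.4, 0.3), residual = 0.3)
  d <- sample_univariate(pmf, 2e4, seed = 13)
  nb <- n_beyond_horizon(d)
  expect_within(nb, 2e4 * 0.3, 4 * sqrt(2e4 * 0.3 * 0.7))
  dc <- continuous_time_correction(d, seed = 14)
  expect_true(all(is.na(dc$times[is.na(d$categories)])))
  expect_false(is.na(mean(dc)))
  expect_error(probability_matrix(matrix(c(0.5, 0.4), 1)), "sum to 1")
})
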