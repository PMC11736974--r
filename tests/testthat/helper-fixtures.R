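# shared fixtures, all built in code

# a random but valid hazard grid (mixed magnitudes, occasional zeros)
random_hazard_grid <- function(len = NULL, delta_t = NULL) {
  len <- if (is.null(len)) sample(1:60, 1) else len
  delta_t <- if (is.null(delta_t)) stats::runif(1, 0.05, 2) else delta_t
  h <- stats::rexp(len, 5)
  h[stats::runif(len) < 0.1] <- 0
  hazard_grid(h, delta_t = delta_t)
}

# pmf of a constant-hazard (exponential) grid
exponential_pmf <- function(rate, delta_t = 1, n_int = 400) {
  event_pmf_from(hazard_grid(rep(rate, n_int), delta_t = delta_t))
}

# write a small life-table CSV and return its path
write_lifetable_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

expect_within <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
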