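test_that("exact power law is recovered perfectly", {
  s <- analyte_series(c(1, 10, 100), c(100, 10, 1), "x")
  f <- fit_power(s)
  expect_equal(f$amplitude, 100)
  expect_equal(f$exponent, -1)
  expect_equal(f$decay_constant, 1)
  expect_equal(f$r_squared, 1)
  expect_false(f$flagged)
})

test_that("constant series reports no decay", {
  s <- analyte_series(c(1, 10, 100), c(10, 10, 10), "c")
  for (fit in list(fit_power(s), fit_exponential(s), fit_linear(s))) {
    expect_equal(fit$exponent, 0)
    expect_equal(fit$r_squared, 0)
    expect_equal(fit$p_slope, 1)
    expect_true(fit$flagged)
  }
  expect_equal(fit_power(s)$decay_constant, 0)
})

test_that("exact exponential and linear models are recovered", {
  t <- c(0, 10, 20)
  fe <- fit_exponential(analyte_series(t, 50 * exp(-0.1 * t), "e"))
  expect_equal(fe$exponent, -0.1)
  expect_equal(fe$amplitude, 50)
  expect_equal(fe$r_squared, 1)
  expect_true(is.na(fe$decay_constant))

  fl <- fit_linear(analyte_series(1:3, 10 - 0.5 * (1:3), "l"))
  expect_equal(fl$exponent, -0.5)
  expect_equal(fl$amplitude, 10)
  expect_equal(fl$r_squared, 1)
})

test_that("log-log OLS matches the brute-force grid-search oracle", {
  set.seed(7)
  for (i in 1:5) {
    ages <- sort(runif(20, 1, 200))
    s <- simulate_profile(ages, 10^runif(1, 3, 7), -runif(1, 0.2, 2),
                          sigma_log = 0.3)
    f <- fit_power(s)
    oracle <- grid_search_loglog(s$points$age, s$points$value)
    expect_equal(f$exponent, unname(oracle["slope"]), tolerance = 1e-6)
    expect_equal(log(f$amplitude), unname(oracle["intercept"]),
                 tolerance = 1e-6)
  }
})

test_that("semi-log and raw-space OLS match the normal-equations oracle", {
  set.seed(8)
  ages <- sort(runif(15, 0, 100))
  y_exp <- 50 * exp(-0.05 * ages) * exp(rnorm(15, 0, 0.2))
  fe <- fit_exponential(analyte_series(ages, y_exp, "e"))
  oe <- ols_closed_form(ages, log(y_exp))
  expect_equal(fe$exponent, unname(oe["slope"]), tolerance = 1e-10)

  y_lin <- 30 - 0.2 * ages + rnorm(15, 0, 1)
  fl <- fit_linear(analyte_series(ages, pmax(y_lin, 0), "l"))
  ol <- ols_closed_form(ages, pmax(y_lin, 0))
  expect_equal(fl$exponent, unname(ol["slope"]), tolerance = 1e-10)
  expect_equal(fl$amplitude, unname(ol["intercept"]), tolerance = 1e-10)
})

test_that("rescaling values changes only the amplitude", {
  set.seed(9)
  s <- simulate_profile(seq(1, 180, length.out = 20), 1e6, -1.2,
                        sigma_log = 0.3)
  f1 <- fit_power(s)
  s2 <- analyte_series(s$points$age, s$points$value * 37.5, "scaled")
  f2 <- fit_power(s2)
  expect_equal(f2$exponent, f1$exponent)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_equal(f2$p_slope, f1$p_slope)
  expect_equal(f2$amplitude, f1$amplitude * 37.5)
})

test_that("zero handling: exclusion vs pseudo-value policies", {
  ages <- c(1, 5, 10, 50, 100)
  vals <- c(100, 20, 0, 2, 1)
  s <- analyte_series(ages, vals, "z")
  f <- fit_power(s)
  expect_equal(f$n_points, 4L)
  expect_equal(f$n_excluded, 1L)
  fp <- fit_power(s, zero_policy = "pseudo")
  expect_equal(fp$n_points, 5L)     # zero replaced by half the smallest value
  expect_equal(min(fp$data$value), 0.5)
  expect_error(fit_power(analyte_series(c(1, 2, 0), c(3, 0, 5), "few")),
               "insufficient data")
})

test_that("flag_fit applies strict thresholds", {
  expect_true(flag_fit(list(p_slope = 0.2, r_squared = 0.5)))
  expect_true(flag_fit(list(p_slope = 0.01, r_squared = 0.1)))
  expect_false(flag_fit(list(p_slope = 0.01, r_squared = 0.9)))
  expect_false(flag_fit(list(p_slope = 0.05, r_squared = 0.2)))  # boundary
})

test_that("compare_models picks the generating model and breaks ties to power", {
  t <- c(1, 5, 10, 50, 100)
  cmp_pow <- compare_models(analyte_series(t, 100 * t^-1, "pow"))
  expect_equal(cmp_pow$best, "power")
  expect_equal(cmp_pow$fits[[1]]$r_squared, 1)
  cmp_lin <- compare_models(analyte_series(t, 200 - 1.5 * t, "lin"))
  expect_equal(cmp_lin$best, "linear")
  # constant series: all three tie at R^2 = 0 -> power preferred
  cmp_const <- compare_models(analyte_series(t, rep(5, 5), "const"))
  expect_equal(cmp_const$best, "power")
})

test_that("decay_fit methods are coherent", {
  set.seed(10)
  s <- simulate_profile(seq(1, 180, length.out = 20), 1e6, -1.2,
                        sigma_log = 0.3, analyte_id = "m")
  f <- fit_power(s)
  expect_named(coef(f), c("amplitude", "exponent"))
  expect_equal(predict(f, age = 1), f$amplitude)
  expect_equal(length(residuals(f)), f$n_points)
  # fitted-space residuals are the log-space OLS residuals
  expect_equal(sum(residuals(f)), 0, tolerance = 1e-10)
  expect_output(print(f), "decay_fit")
  expect_output(summary(f), "residual SD")
  reps <- simulate(f, nsim = 2, seed = 1)
  expect_length(reps, 2L)
  expect_equal(reps[[1]]$points$age, f$data$age)
  # same seed -> same draw
  expect_equal(simulate(f, seed = 1)[[1]], reps[[1]])
  tab <- as.data.frame(f)
  expect_equal(tab$decay_constant, 1.2, tolerance = 0.2)
})

test_that("nls refinement stays close to the OLS solution on clean data", {
  set.seed(11)
  s <- simulate_profile(seq(1, 100, length.out = 20), 1000, -1,
                        sigma_log = 0.05)
  f_ols <- fit_power(s)
  f_nls <- fit_power(s, method = "nls")
  expect_equal(f_nls$exponent, f_ols$exponent, tolerance = 0.05)
})
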