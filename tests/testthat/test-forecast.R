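# ARIMA fitting, AIC order selection, half-split validation, cutoff forecast.

test_that("AR(1) coefficient is recovered from simulated data", {
  y <- sim_ar(500, 0.7, seed = 42)
  f <- fit_arima(y, c(1, 0, 0))
  expect_true(f$converged)
  expect_lt(abs(unname(f$coefficients["ar1"]) - 0.7), 0.1)
})

test_that("white-noise log-likelihood matches the analytic Gaussian value", {
  y <- granumix:::with_local_seed(7, rnorm(300, 5, 2))
  f <- fit_arima(y, c(0, 0, 0))
  mu <- mean(y)
  s2 <- mean((y - mu)^2)  # Gaussian MLE of the variance
  ll <- sum(dnorm(y, mu, sqrt(s2), log = TRUE))
  expect_equal(f$log_likelihood, ll, tolerance = 1e-6)
  # AIC identity with k = 2 estimated parameters (mean, variance)
  expect_equal(f$aic, 2 * 2 - 2 * f$log_likelihood)
})

test_that("AIC identity 2k - 2 logLik holds for every reported fit", {
  y <- sim_ar(200, c(0.5, 0.2), seed = 5, mean = 1.4)
  for (ord in list(c(1, 0, 0), c(2, 0, 1), c(0, 1, 1))) {
    f <- fit_arima(y, ord)
    if (!f$converged) next
    k <- length(f$coefficients) + 1
    expect_equal(f$aic, 2 * k - 2 * f$log_likelihood)
  }
})

test_that("a linear ramp is annihilated by one differencing operation", {
  y <- seq(1, 3, length.out = 80)
  f <- fit_arima(y, c(0, 1, 0))
  expect_true(f$degenerate)
  expect_equal(f$sigma2, 0)
  # and the degenerate fit continues the ramp deterministically
  step <- diff(y)[1]
  fc <- forecast_arima(f, 3)
  expect_equal(fc$mean, 3 + step * (1:3))
})

test_that("too-short series raise an explicit length error", {
  expect_error(fit_arima(c(1, 2, 3), c(5, 0, 0)), "too short")
})

test_that("AIC ties break toward the lower p + q, then lower p", {
  mk <- function(p, q, aic) list(order = c(p, 0, q), aic = aic)
  expect_true(granumix:::aic_preferred(mk(0, 0, 10), mk(1, 0, 12)))
  expect_false(granumix:::aic_preferred(mk(0, 0, 12), mk(1, 0, 10)))
  expect_true(granumix:::aic_preferred(mk(1, 0, 10), mk(0, 2, 10)))   # p+q 1 < 2
  expect_true(granumix:::aic_preferred(mk(0, 1, 10), mk(1, 0, 10)))   # same p+q, lower p
  expect_false(granumix:::aic_preferred(mk(1, 0, 10), mk(0, 1, 10)))
})

test_that("white noise is selected without material autocorrelation structure", {
  # AIC minimization over ~50 candidate orders has a well-known positive
  # probability of admitting a small spurious term on pure noise; the robust
  # parsimony properties are that no differencing is selected and that the
  # winner's AIC gain over the (0,0,0) null stays below any material size
  n_rep <- 25
  d_zero <- 0
  no_material_gain <- 0
  for (r in seq_len(n_rep)) {
    y <- granumix:::with_local_seed(2000 + r, rnorm(200))
    f <- select_order_aic(y, p_max = 6, patience = 4)
    null_sel <- fit_arima(y, c(0, 0, 0))$selection_aic
    if (f$order[2] == 0) d_zero <- d_zero + 1
    if (null_sel - f$selection_aic < 6) no_material_gain <- no_material_gain + 1
  }
  expect_gte(d_zero / n_rep, 0.8)
  expect_equal(no_material_gain, n_rep)
})

test_that("the search log records attempted orders and failure lists them", {
  y <- sim_ar(120, 0.5, seed = 3)
  f <- select_order_aic(y, p_max = 4, patience = 2)
  log <- attr(f, "search_log")
  expect_true(all(c("p", "d", "q", "aic", "converged") %in% names(log)))
  expect_gt(nrow(log), 5)
})

test_that("half-split validation is tight on smooth decay and exact on constants", {
  ser <- generate_mixing_curve(psi0 = 1.9, rate_k = 0.5, rpm = 30,
                               noise_sd = 0, n_points = 120)
  v <- validate_half_split(ser, p_max = 6, patience = 4)
  expect_lt(v$mape, 0.5)

  vc <- validate_half_split(rep(1.37, 40), p_max = 2)
  expect_equal(vc$mape, 0)
  expect_error(validate_half_split(rnorm(10)), "at least 20")
})

test_that("forecasting zero steps leaves the training state untouched", {
  f <- fit_arima(sim_ar(100, 0.5, seed = 9), c(1, 0, 0))
  fc <- forecast_arima(f, 0)
  expect_equal(nrow(fc), 0)
})

test_that("an observed dip below the cutoff short-circuits the forecast", {
  t <- seq(0, 10, by = 0.5)
  y <- 2 - 0.1 * t  # crosses 1.1 at t = 9 exactly
  est <- forecast_to_cutoff(data.frame(t = t, psi = y), cutoff = 1.1)
  expect_true(est$crossed_in_observed)
  expect_equal(est$t_end, 9)
})

test_that("noiseless exponential decay recovers the closed-form crossing", {
  k <- 0.35
  t_cross <- log(9) / k  # 1 + 0.9 exp(-k t) = 1.1
  t <- seq(0, 0.62 * t_cross, length.out = 100)  # trained pre-crossing
  est <- forecast_to_cutoff(data.frame(t = t, psi = 1 + 0.9 * exp(-k * t)),
                            cutoff = 1.1, p_max = 6, patience = 4)
  expect_false(est$crossed_in_observed)
  expect_lt(abs(est$t_end - t_cross) / t_cross, 0.05)
  expect_false(is.null(est$order))  # selected order is reported
  expect_lte(nrow(est$forecast_path), est$horizon_cap)
})

test_that("nondecreasing series yield an explicit no-crossing result", {
  t <- seq(0, 5, length.out = 60)
  y <- 1.5 + 0.01 * t + granumix:::with_local_seed(4, rnorm(60, 0, 1e-4))
  est <- forecast_to_cutoff(data.frame(t = t, psi = y), cutoff = 1.1,
                            horizon_cap = 300, p_max = 4, patience = 3)
  expect_true(est$no_crossing)
  expect_true(is.na(est$t_end))
  expect_equal(est$horizon_cap, 300)
})

test_that("crossing time is invariant under joint scaling of deviation and cutoff", {
  k <- 0.4
  t <- seq(0, 4, length.out = 90)
  base <- 1 + 0.9 * exp(-k * t)
  est1 <- forecast_to_cutoff(data.frame(t = t, psi = base), cutoff = 1.1,
                             p_max = 5, patience = 3)
  for (c_scale in c(0.5, 2)) {
    yc <- 1 + c_scale * (base - 1)
    estc <- forecast_to_cutoff(data.frame(t = t, psi = yc),
                               cutoff = 1 + c_scale * 0.1,
                               p_max = 5, patience = 3)
    expect_equal(estc$t_end, est1$t_end, tolerance = 1e-2)
  }
})

test_that("endpoint reports serialize to JSON", {
  est <- forecast_to_cutoff(data.frame(t = 0:20, psi = 2 - 0.05 * (0:20)),
                            cutoff = 1.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_endpoint_report(est, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$t_end, est$t_end)
  expect_true(rep$crossed_in_observed)
})
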