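make_test_design <- function(n = 50, seed = 42, theta = 5) {
  set.seed(seed)
  X <- cbind(1, rnorm(n), runif(n), rbinom(n, 1, 0.4))
  colnames(X) <- c("(Intercept)", "x1", "x2", "x3")
  eta <- 0.5 + 0.3 * X[, 2] - 0.2 * X[, 3] + 0.4 * X[, 4]
  list(X = X, y = rnbinom(n, size = theta, mu = exp(eta)))
}

test_that("Poisson limit without penalty matches a stats::glm oracle", {
  d <- make_test_design()
  y <- rpois(length(d$y), exp(0.4 + 0.2 * d$X[, 2]))
  f <- fit_penalized_nb_glm(list(y = y, X = d$X), lambda = 0,
                            theta = 1e10, tol = 1e-14)
  g <- glm(y ~ d$X - 1, family = poisson(),
           control = list(epsilon = 1e-14))
  expect_lt(max(abs((f$coefficients - coef(g)) / coef(g))), 1e-8)
  ## covariance agrees with the unpenalized information matrix
  expect_equal(unname(f$cov), unname(vcov(g)), tolerance = 1e-3)
})

test_that("intercept-only NB fit recovers log of the mean exactly", {
  f <- fit_penalized_nb_glm(list(y = c(2, 4, 6), X = matrix(1, 3, 1)),
                            lambda = 0, theta = 3, tol = 1e-14)
  expect_equal(unname(f$coefficients), log(4), tolerance = 1e-10)
})

test_that("penalized IRLS matches the textbook IRLS and BFGS oracles", {
  d <- make_test_design(n = 60, seed = 7, theta = 4)
  ## (a) fixed theta, no penalty: independent textbook IRLS
  f <- fit_penalized_nb_glm(list(y = d$y, X = d$X), lambda = 0,
                            theta = 4, tol = 1e-14)
  expect_equal(unname(f$coefficients),
               unname(oracle_irls_nb(d$y, d$X, 4)), tolerance = 1e-7)
  ## (b) with a penalty: direct quasi-Newton maximization of the
  ## penalized NB log-likelihood
  S <- diag(c(0, 1, 1, 1))
  lam <- 3
  fp <- fit_penalized_nb_glm(list(y = d$y, X = d$X, S = S), lambda = lam,
                             theta = 4, tol = 1e-14)
  negpl <- function(b)
    -sum(dnbinom(d$y, size = 4, mu = exp(pmin(d$X %*% b, 30)),
                 log = TRUE)) + lam / 2 * drop(t(b) %*% S %*% b)
  o <- optim(rep(0, 4), negpl, method = "BFGS",
             control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(max(abs(fp$coefficients - o$par)), 1e-6)
  expect_error(fit_penalized_nb_glm(list(y = d$y, X = d$X), lambda = -1,
                                    theta = 4), "lambda")
})

test_that("smoothing limits: infinite penalty collapses spline to a line", {
  sim <- simulate_study(420, seed = 21)
  study <- build_study_panel(sim$exposure, sim$weather, sim$visits)
  des <- assemble_design(study, model_spec("single", "pm25", "0"))
  f_inf <- fit_nb_gam(des, lambda = 1e9, theta = 10)
  expect_lt(abs(f_inf$spline_edf - 2), 0.05)
  ## fitted spline component is linear in time
  spl <- des$spline_idx
  comp <- drop(des$X[, spl] %*% f_inf$coefficients[spl])
  tt <- as.numeric(des$dates - des$dates[1])
  lin <- lm(comp ~ tt)
  expect_lt(max(abs(residuals(lin))), 1e-4 * (max(comp) - min(comp) + 1))
})

test_that("smoothness selection tracks trend curvature", {
  curved <- simulate_study(900, seed = 5,
                           truth = true_params(trend_amplitude = 0.35,
                                               trend_period_days = 400))
  study_c <- build_study_panel(curved$exposure, curved$weather,
                               curved$visits)
  fit_c <- fit_nb_gam(assemble_design(study_c,
                                      model_spec("single", "pm25", "0")),
                      control = sim_fit_control())
  expect_gt(fit_c$spline_edf, 2.5)
  flat <- simulate_study(900, seed = 5,
                         truth = true_params(trend_amplitude = 0))
  study_f <- build_study_panel(flat$exposure, flat$weather, flat$visits)
  fit_f <- fit_nb_gam(assemble_design(study_f,
                                      model_spec("single", "pm25", "0")),
                      control = sim_fit_control())
  expect_lt(abs(fit_f$spline_edf - 2), 0.5)
  ## optimality on a bracketing grid: the returned smoothing parameter
  ## beats 10 log-spaced alternatives on its own criterion
  des <- assemble_design(study_c, model_spec("single", "pm25", "0"))
  crit <- function(lam) {
    ft <- fit_nb_gam(des, lambda = lam, theta = fit_c$nb_dispersion)
    ft$criterion_value
  }
  at_opt <- crit(fit_c$smoothing_parameter)
  grid <- exp(seq(log(fit_c$smoothing_parameter) - 3,
                  log(fit_c$smoothing_parameter) + 3, length.out = 10))
  expect_true(all(at_opt <= vapply(grid, crit, numeric(1)) + 1e-6))
})

test_that("scaling equivariance and time-shift invariance", {
  sim <- simulate_study(420, seed = 13)
  study <- build_study_panel(sim$exposure, sim$weather, sim$visits)
  f5 <- fit_nb_gam(assemble_design(study, model_spec("single", "pm25",
                                                     "0", pm_scale = 5)),
                   lambda = 10, theta = 12)
  f10 <- fit_nb_gam(assemble_design(study, model_spec("single", "pm25",
                                                      "0", pm_scale = 10)),
                    lambda = 10, theta = 12)
  i <- which(f5$roles == "pm")
  j <- which(f5$roles == "pm_wf")
  ## halving the column scale (pm/10 vs pm/5) doubles the coefficient
  expect_equal(f10$coefficients[[i]], 2 * f5$coefficients[[i]],
               tolerance = 1e-6)
  expect_equal(f10$coefficients[[j]], 2 * f5$coefficients[[j]],
               tolerance = 1e-6)
  expect_equal(f10$fitted, f5$fitted, tolerance = 1e-8)
  ## adding a constant to the time index leaves all non-spline
  ## coefficients unchanged (knots shift with the index)
  study2 <- study
  study2$data$time <- study2$data$time + 5000
  f_shift <- fit_nb_gam(assemble_design(study2,
                                        model_spec("single", "pm25", "0",
                                                   pm_scale = 5)),
                        lambda = 10, theta = 12)
  keep <- f5$roles != "spline"
  expect_equal(f_shift$coefficients[keep], f5$coefficients[keep],
               tolerance = 1e-6)
  expect_equal(f_shift$fitted, f5$fitted, tolerance = 1e-6)
})

test_that("rank deficiency raises an error naming offending columns", {
  ## two monitors with identical activity windows produce identical
  ## (non-constant) activity indicator columns
  n <- 420
  cal <- generate_wildfire_calendar(n, seed = 3)
  pan <- generate_monitor_panel(cal, n_monitors = 3, seed = 3,
                                activity_windows = list(c(1L, n),
                                                        c(60L, n),
                                                        c(60L, n)),
                                weights = c(5, 2, 1), dropout_rate = 0)
  w <- generate_weather(n, seed = 3)
  ep <- build_exposure_panel(pan, cal)
  v <- generate_visits(ep, w, cal, true_params(), seed = 3)
  study <- build_study_panel(ep, w, v)
  expect_error(assemble_design(study, model_spec("single", "pm25", "0")),
               "mon_pm25_M0", class = "smokegam_rank_error")
})

test_that("residual ACF: white noise, ACF(0), AR(1) recovery", {
  sim <- simulate_study(600, seed = 17)
  study <- build_study_panel(sim$exposure, sim$weather, sim$visits)
  fit <- fit_nb_gam(assemble_design(study, model_spec("single", "pm25",
                                                      "0")),
                    control = sim_fit_control())
  r <- residual_acf(fit, max_lag = 25)
  expect_equal(r$acf[1], 1)
  expect_equal(r$band, 1.96 / sqrt(length(fit$fitted)))
  ## a correctly specified model leaves ~white residuals
  expect_gt(mean(abs(r$acf[-1]) < r$band), 0.8)
  ## AR(1)-contaminated residuals show rho at lag 1
  fit2 <- fit
  set.seed(8)
  e <- as.numeric(arima.sim(list(ar = 0.5), length(fit$fitted)))
  fit2$residuals_deviance <- e
  r2 <- residual_acf(fit2, max_lag = 5)
  expect_lt(abs(r2$acf[2] - 0.5), 0.15)
  expect_error(residual_acf(fit, max_lag = length(fit$fitted)),
               "max_lag")
})

test_that("theta estimation recovers the generating dispersion", {
  sim <- simulate_study(2192, seed = 19)
  study <- build_study_panel(sim$exposure, sim$weather, sim$visits)
  fit <- fit_nb_gam(assemble_design(study, model_spec("single", "pm25",
                                                      "0")),
                    control = sim_fit_control())
  expect_gt(fit$nb_dispersion, 6)
  expect_lt(fit$nb_dispersion, 25)  # true size 12
  expect_true(fit$converged)
  ## covariance is symmetric PSD; spline edf within its range
  ev <- eigen(fit$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_gte(fit$spline_edf, 2 - 1e-6)
  expect_lte(fit$spline_edf, fit$spec$spline_basis_size)
})
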