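test_that("wildfire calendar: degenerate cases and validation", {
  expect_error(generate_wildfire_calendar(0), "n_days")
  cal0 <- generate_wildfire_calendar(365, episode_rate = 0, seed = 1)
  expect_true(all(cal0$smoke_hours == 0L) && !any(cal0$wf_day))
  ## degenerate length distribution: every episode is 7 consecutive days
  cal7 <- generate_wildfire_calendar(2000, episode_rate = 1,
                                     episode_length_dist = 7, seed = 4)
  runs <- rle(cal7$wf_day)
  expect_true(all(runs$lengths[runs$values] %% 7 == 0))
  expect_true(all(cal7$smoke_hours >= 0 & cal7$smoke_hours <= 24))
})

test_that("wildfire calendar: smoke days cluster warm-season, mostly >20h", {
  ## central tendency over many seeds: six-year total near the observed
  ## scale (within +-50% of 188)
  totals <- vapply(1:60, function(s)
    sum(generate_wildfire_calendar(2192, seed = s)$wf_day), numeric(1))
  expect_gt(mean(totals), 188 * 0.5)
  expect_lt(mean(totals), 188 * 1.5)
  cal <- generate_wildfire_calendar(2192, seed = 11)
  hrs <- cal$smoke_hours[cal$wf_day]
  expect_gt(mean(hrs > 20), 0.75)
  month <- as.integer(format(cal$date[cal$wf_day], "%m"))
  expect_gt(mean(month %in% 5:10), 0.8)
})

test_that("monitor panel: structure, wildfire contamination, additivity", {
  cal <- generate_wildfire_calendar(900, seed = 2)
  pan <- generate_monitor_panel(cal, seed = 2)
  d <- pan$data
  wide <- reshape(d, idvar = c("monitor_id", "date"),
                  timevar = "fraction", direction = "wide")
  ok <- !is.na(wide$value.pm25) & !is.na(wide$value.pm_coarse) &
    !is.na(wide$value.pm10)
  expect_equal(wide$value.pm10[ok],
               wide$value.pm25[ok] + wide$value.pm_coarse[ok])
  expect_true(all(d$value >= 0, na.rm = TRUE))
  expect_true(all(is.na(d$value[d$active == 0L])))
  ## wildfire days raise PM2.5 by well over 1.5x
  ep <- build_exposure_panel(pan, cal)
  e <- ep$data
  expect_gt(mean(e$pm25[e$wf_day], na.rm = TRUE) /
              mean(e$pm25[!e$wf_day], na.rm = TRUE), 1.5)
  ## spike is concentrated on the fine fraction
  bump_f <- mean(e$pm25[e$wf_day], na.rm = TRUE) -
    mean(e$pm25[!e$wf_day], na.rm = TRUE)
  bump_c <- mean(e$pm_coarse[e$wf_day], na.rm = TRUE) -
    mean(e$pm_coarse[!e$wf_day], na.rm = TRUE)
  expect_gt(bump_f, 3 * max(bump_c, 0.1))
})

test_that("monitor panel: null contamination and argument errors", {
  cal <- generate_wildfire_calendar(400, seed = 3)
  pan <- generate_monitor_panel(cal, seed = 3, spike_scale = 0,
                                coarse_bump = 0, dropout_rate = 0)
  ep <- build_exposure_panel(pan, cal)
  e <- ep$data
  ## with no spike, wildfire and non-wildfire PM2.5 agree in expectation;
  ## compare within the warm season so the seasonal baseline (winter
  ## inversions) does not masquerade as a smoke effect
  warm <- as.integer(format(e$date, "%m")) %in% 6:9
  expect_lt(abs(mean(e$pm25[e$wf_day & warm]) /
                  mean(e$pm25[!e$wf_day & warm]) - 1), 0.35)
  expect_error(generate_monitor_panel(cal, n_monitors = 2,
                                      weights = c(1, 2, 3),
                                      activity_windows = list(c(1, 400))),
               "one activity window")
})

test_that("weather: ordering, correlation, degenerate amplitude", {
  w <- generate_weather(2190, seed = 8)
  expect_true(all(w$temp_min <= w$temp_mean & w$temp_mean <= w$temp_max))
  expect_true(cor(w$temp_mean, w$rh_mean) > -0.9 &&
                cor(w$temp_mean, w$rh_mean) < -0.6)
  wc <- generate_weather(100, seed = 1, amplitude = 0, noise_sd = 0)
  expect_equal(length(unique(wc$temp_mean)), 1L)
})

test_that("visits: null-effects mean, Poisson limit, AR contribution", {
  n <- 2190
  cal <- generate_wildfire_calendar(n, episode_rate = 0, seed = 1)
  pan <- generate_monitor_panel(cal, seed = 1, dropout_rate = 0)
  w <- generate_weather(n, seed = 1)
  ep <- build_exposure_panel(pan, cal)
  null_truth <- true_params(intercept = log(8.6), dow_effects = rep(0, 6),
                            holiday_effects = 0, trend_amplitude = 0,
                            temp_coef = 0, ar_coefs = rep(0, 10),
                            beta1_pm = 0, beta2_interaction = 0,
                            beta3_wf = 0)
  v <- generate_visits(ep, w, cal, null_truth, seed = 9)
  ## NB sampling error of the mean over 2190 days: sd ~ sqrt(mu(1+mu/th)/n)
  tol <- 4 * sqrt(8.6 * (1 + 8.6 / 12) / n)
  expect_lt(abs(mean(v$visits) - 8.6), tol)
  ## dispersion -> large: variance approaches the mean (Poisson limit)
  pois_truth <- true_params(intercept = log(8.6), dow_effects = rep(0, 6),
                            holiday_effects = 0, trend_amplitude = 0,
                            temp_coef = 0, ar_coefs = rep(0, 10),
                            beta1_pm = 0, beta2_interaction = 0,
                            beta3_wf = 0, nb_dispersion = 1e8)
  vp <- generate_visits(ep, w, cal, pois_truth, seed = 9)
  expect_lt(abs(var(vp$visits) / mean(vp$visits) - 1), 0.15)
})

test_that("visits: wildfire terms shift the log rate as specified", {
  n <- 1200
  cal <- generate_wildfire_calendar(n, seed = 6)
  pan <- generate_monitor_panel(cal, seed = 6, dropout_rate = 0)
  w <- generate_weather(n, seed = 6)
  ep <- build_exposure_panel(pan, cal)
  base <- true_params(beta1_pm = 0.01, beta2_interaction = 0.06,
                      beta3_wf = -0.02, nb_dispersion = 1e7,
                      ar_coefs = rep(0, 10))
  null <- true_params(beta1_pm = 0.01, beta2_interaction = 0,
                      beta3_wf = 0, nb_dispersion = 1e7,
                      ar_coefs = rep(0, 10))
  ## analytic linear predictors differ by b2*(PM/5) + b3 on wildfire days:
  ## compare log of conditional expectations via large-theta realizations
  v1 <- generate_visits(ep, w, cal, base, seed = 2)
  v0 <- generate_visits(ep, w, cal, null, seed = 2)
  wf <- cal$wf_day
  expected <- 0.06 * ep$data$pm25[wf] / 5 - 0.02
  observed <- log(v1$visits[wf] + 0.5) - log(v0$visits[wf] + 0.5)
  expect_lt(abs(mean(observed) - mean(expected)), 0.1)
  ## non-wildfire days share the same linear predictor: no systematic shift
  off_wf <- log(v1$visits[!wf] + 0.5) - log(v0$visits[!wf] + 0.5)
  expect_lt(abs(mean(off_wf)), 0.06)
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_study(220, seed = 77)
  s2 <- simulate_study(220, seed = 77)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$panel$data, s2$panel$data)
  expect_identical(s1$weather, s2$weather)
  ## and all tables share one date index
  expect_identical(s1$calendar$date, s1$weather$date)
  expect_identical(s1$calendar$date, s1$exposure$data$date)
  expect_identical(s1$calendar$date, s1$visits$date)
})

test_that("true_params validates dispersion and finiteness", {
  expect_error(true_params(nb_dispersion = 0), "nb_dispersion")
  expect_error(true_params(beta1_pm = Inf), "finite")
  ## default long-run mean in a plausible clinical range
  sim <- simulate_study(1100, seed = 12)
  expect_gt(mean(sim$visits$visits), 1)
  expect_lt(mean(sim$visits$visits), 50)
})
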