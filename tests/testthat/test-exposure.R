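dates10 <- as.Date("2015-06-01") + 0:9

test_that("classify_wildfire_day: truth table and validation", {
  expect_identical(classify_wildfire_day(c(0L, 1L, 24L)),
                   c(FALSE, TRUE, TRUE))
  expect_error(classify_wildfire_day(25), "0, 24")
  expect_error(classify_wildfire_day(-1), "0, 24")
  expect_error(classify_wildfire_day(2.5), "integers")
})

test_that("weighted daily exposure: hand arithmetic and renormalization", {
  vals <- list(cbind(pm25 = rep(10, 10), pm_coarse = rep(5, 10),
                     pm10 = rep(15, 10)),
               cbind(pm25 = rep(20, 10), pm_coarse = rep(7, 10),
                     pm10 = rep(27, 10)))
  p <- tiny_panel(dates10, vals, weights = c(3, 1))
  w <- weighted_daily_exposure(p, "pm25")
  expect_equal(w$value, rep(12.5, 10))  # (3*10 + 1*20)/4
  ## equal weights: symmetry
  pe <- tiny_panel(dates10, vals, weights = c(2, 2))
  expect_equal(weighted_daily_exposure(pe, "pm_coarse")$value, rep(6, 10))
  ## single-monitor identity
  p1 <- tiny_panel(dates10, vals[1])
  expect_equal(weighted_daily_exposure(p1, "pm25")$value, rep(10, 10))
  ## invariance to rescaling all weights
  pk <- tiny_panel(dates10, vals, weights = c(300, 100))
  expect_equal(weighted_daily_exposure(pk, "pm25")$value, w$value)
  ## weights renormalize daily over the active subset; missing if none
  act <- list(matrix(1L, 10, 3),
              {
                a <- matrix(1L, 10, 3); a[5, ] <- 0L; a
              })
  pa <- tiny_panel(dates10, vals, active = act, weights = c(3, 1))
  wa <- weighted_daily_exposure(pa, "pm25")
  expect_equal(wa$value[5], 10)
  none <- list({
    a <- matrix(1L, 10, 3); a[7, ] <- 0L; a
  })
  pn <- tiny_panel(dates10, vals[1], active = none)
  expect_true(is.na(weighted_daily_exposure(pn, "pm25")$value[7]))
  expect_error(weighted_daily_exposure(p, "pm1"), "fraction")
})

test_that("rolling lag averages propagate missingness", {
  x <- c(10, 20, 30, NA, 50, 60, 70)
  expect_identical(rolling_lag_average(x, "0"), x)
  l02 <- rolling_lag_average(x, "0-2")
  expect_true(all(is.na(l02[1:2])))
  expect_equal(l02[3], 20)
  expect_true(all(is.na(l02[4:6])))  # any missing lag => missing
  expect_equal(l02[7], 60)
  expect_true(all(is.na(rolling_lag_average(x, "0-6")[1:6])))
  expect_error(rolling_lag_average(x, "0-3"), "lag set")
})

test_that("tri-state wildfire indicator: truth table", {
  wf <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  i0 <- wildfire_lag_indicator(wf, "0")
  expect_identical(i0, as.integer(wf))
  i02 <- wildfire_lag_indicator(wf, "0-2")
  expect_true(all(is.na(i02[1:2])))
  expect_identical(i02[3:8],
                   c(0L, WF_EXCLUDED, WF_EXCLUDED, 1L, WF_EXCLUDED,
                     WF_EXCLUDED))
  i06 <- wildfire_lag_indicator(rep(TRUE, 7), "0-6")
  expect_identical(i06[7], 1L)
  ## monotone totals across lag sets on generated calendars
  for (s in 1:5) {
    cal <- generate_wildfire_calendar(1500, seed = s)
    n1 <- vapply(c("0", "0-2", "0-6"), function(ls)
      sum(wildfire_lag_indicator(cal$wf_day, ls) == 1L, na.rm = TRUE),
      numeric(1))
    expect_true(n1[1] >= n1[2] && n1[2] >= n1[3])
  }
})

test_that("exceedance exclusion: strict inequality, PM2.5 only", {
  pm <- c(10, 20, 40.4, 39, 50.0, 40.4, 12)
  ind <- c(0L, 0L, 0L, 1L, 1L, 1L, 0L)
  m <- exceedance_exclusion(pm, ind)
  expect_equal(attr(m, "threshold"), 40.4)
  expect_identical(as.logical(m), c(FALSE, FALSE, FALSE, FALSE, TRUE,
                                    FALSE, FALSE))  # 40.4 retained
  ## EXCLUDED observations are never masked by this rule
  ind2 <- c(0L, WF_EXCLUDED, 0L, 1L, 1L, WF_EXCLUDED, 0L)
  m2 <- exceedance_exclusion(pm, ind2)
  expect_false(any(m2[ind2 == WF_EXCLUDED]))
  expect_error(exceedance_exclusion(c(1, 2), c(1L, 1L)), "threshold")
})

test_that("exceedance exclusion: toy panel with known count", {
  ind <- c(rep(0L, 50), rep(1L, 10))
  pm <- c(seq(2, 30, length.out = 50),            # non-wildfire, max 30
          c(25, 28, 29.9, 31, 35, 50, 12, 8, 22, 21))  # 10 wildfire days
  m <- exceedance_exclusion(pm, ind)
  expect_equal(attr(m, "threshold"), 30)
  expect_equal(sum(m), 3L)  # exactly 31, 35, 50 exceed the threshold
})

test_that("monitor activity indicators: any-lag rule", {
  act <- list(matrix(1L, 10, 3),
              {
                a <- matrix(0L, 10, 3); a[4, ] <- 1L; a
              },
              matrix(0L, 10, 3))
  vals <- replicate(3, cbind(pm25 = rep(5, 10), pm_coarse = rep(5, 10),
                             pm10 = rep(10, 10)), simplify = FALSE)
  p <- tiny_panel(dates10, vals, active = act)
  m0 <- monitor_activity_indicators(p, "pm25", "0")
  expect_equal(unname(m0[, 1]), rep(1L, 10))
  expect_equal(unname(m0[, 3]), rep(0L, 10))
  expect_equal(which(m0[, 2] == 1L), 4L)
  ## active only at t-1 still counts at t for lags 0-2
  m02 <- monitor_activity_indicators(p, "pm25", "0-2")
  expect_equal(which(m02[, 2] == 1L), 4:6)
})

test_that("brute-force oracle matches vectorized exposure panel", {
  for (s in c(2, 9)) {
    cal <- generate_wildfire_calendar(30, episode_rate = 30,
                                      episode_length_dist = 4, seed = s)
    pan <- generate_monitor_panel(cal, n_monitors = 3, seed = s,
                                  weights = c(5, 2, 1),
                                  dropout_rate = 0.15)
    ep <- build_exposure_panel(pan, cal)
    for (ls in c("0", "0-2", "0-6")) {
      bf <- brute_exposure(pan, cal, ls)
      sfx <- paste0("l", gsub("-", "", ls))
      for (f in c("pm25", "pm_coarse", "pm10")) {
        expect_equal(ep$data[[f]], bf[[f]])
        expect_equal(ep$data[[paste0(f, "_", sfx)]],
                     bf[[paste0(f, "_avg")]])
      }
      expect_identical(ep$data[[paste0("wf_", sfx)]], bf$wf_ind)
      expect_equal(ep$data[[paste0("excl_", sfx)]], bf$mask)
      expect_equal(unname(ep$thresholds[ls]), attr(bf, "threshold"))
    }
  }
})

test_that("exposure panel invariants on generated data", {
  cal <- generate_wildfire_calendar(800, seed = 14)
  pan <- generate_monitor_panel(cal, seed = 14)
  ep <- build_exposure_panel(pan, cal)
  d <- ep$data
  ## weighted value lies within [min, max] of active monitors that day
  long <- pan$data[pan$data$fraction == "pm25" & pan$data$active == 1L &
                     !is.na(pan$data$value), ]
  rng <- do.call(rbind, tapply(long$value, long$date, range,
                               simplify = FALSE))
  m <- match(rownames(rng), as.character(d$date))
  expect_true(all(d$pm25[m] >= rng[, 1] - 1e-12 &
                    d$pm25[m] <= rng[, 2] + 1e-12))
  ## post-masking max property: every retained wildfire lag-average is
  ## <= the maximum over retained non-wildfire observations
  for (ls in c("0", "0-2", "0-6")) {
    sfx <- paste0("l", gsub("-", "", ls))
    ind <- d[[paste0("wf_", sfx)]]
    excl <- d[[paste0("excl_", sfx)]]
    pm <- d[[paste0("pm25_", sfx)]]
    kept_wf <- !is.na(ind) & ind == 1L & !excl & !is.na(pm)
    max_nonwf <- max(pm[!is.na(ind) & ind == 0L], na.rm = TRUE)
    expect_true(all(pm[kept_wf] <= max_nonwf))
  }
})
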