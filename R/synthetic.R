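#' Ground-truth parameters for the synthetic study generator
#'
#' Collects every parameter of the data-generating count model so that
#' downstream fits can be checked against known truth.  The daily visit
#' count is negative-binomially distributed with log mean
#'
#' `alpha + dow + holidays + trend(t) + zeta * temp7 + sum_j eta_j *
#'  log(1 + y[t-j]) + beta1 * PM/5 + beta2 * (PM/5) * WF + beta3 * WF`
#'
#' where PM is the lag-0 patient-weighted PM2.5 exposure in ug/m3, WF the
#' wildfire-day indicator, and temp7 the trailing 7-day mean of daily mean
#' temperature.  Defaults give a long-run mean of roughly 8-9 visits/day
#' with variance/mean about 1.7 (dispersion 12), matching the scale of an
#' urban ED/urgent-care asthma series.
#'
#' @param intercept baseline log rate.
#' @param dow_effects length-6 log-rate offsets for Monday..Saturday
#'   (Sunday is the reference).
#' @param holiday_effects log-rate offsets for the 17 holiday indicators
#'   (recycled if scalar).
#' @param trend_amplitude amplitude of the smooth long-term trend on the
#'   log-rate scale.
#' @param trend_period_days period of the long-term trend cycle (days).
#' @param seasonal_phase phase offset of the trend, in days.
#' @param temp_coef log-rate change per degree C of 7-day mean temperature
#'   (negative: colder weeks see more visits).
#' @param ar_coefs length-10 coefficients on `log(1 + y[t-j])`, j = 1..10.
#' @param beta1_pm non-wildfire PM2.5 slope, log rate per 5 ug/m3.
#' @param beta2_interaction added wildfire PM2.5 slope, log rate per
#'   5 ug/m3.
#' @param beta3_wf wildfire-day main-effect log-rate offset.
#' @param nb_dispersion negative-binomial size parameter (> 0);
#'   variance = mu + mu^2/size.
#' @param pm_scale ug/m3 per PM unit (5, the analysis scaling).
#' @return an object of class `true_params`.
#' @export
true_params <- function(intercept = 1.85,
                        dow_effects = c(0.08, 0.02, 0.00, -0.02, 0.00,
                                        0.03),
                        holiday_effects = -0.10,
                        trend_amplitude = 0.10,
                        trend_period_days = 1096,
                        seasonal_phase = 0,
                        temp_coef = -0.012,
                        ar_coefs = rep(0.02, 10),
                        beta1_pm = 0.01,
                        beta2_interaction = 0.06,
                        beta3_wf = -0.02,
                        nb_dispersion = 12,
                        pm_scale = 5) {
  stopifnot(length(dow_effects) == 6L, length(ar_coefs) == 10L)
  if (length(holiday_effects) == 1L)
    holiday_effects <- rep(holiday_effects, 17L)
  stopifnot(length(holiday_effects) == 17L)
  if (!is.finite(nb_dispersion) || nb_dispersion <= 0)
    abort("nb_dispersion must be a positive finite number",
          class = "smokegam_argument_error")
  vals <- c(intercept, dow_effects, holiday_effects, trend_amplitude,
            temp_coef, ar_coefs, beta1_pm, beta2_interaction, beta3_wf)
  if (!all(is.finite(vals)))
    abort("all effect magnitudes must be finite",
          class = "smokegam_argument_error")
  structure(list(intercept = intercept, dow_effects = dow_effects,
                 holiday_effects = holiday_effects,
                 trend_amplitude = trend_amplitude,
                 trend_period_days = trend_period_days,
                 seasonal_phase = seasonal_phase,
                 temp_coef = temp_coef, ar_coefs = ar_coefs,
                 beta1_pm = beta1_pm,
                 beta2_interaction = beta2_interaction,
                 beta3_wf = beta3_wf, nb_dispersion = nb_dispersion,
                 pm_scale = pm_scale),
            class = "true_params")
}

#' Generate a wildfire smoke-day calendar
#'
#' Simulates contiguous smoke episodes concentrated in the warm season
#' (episode starts are drawn with a Gaussian day-of-year weight peaking in
#' mid August).  Most smoke days are affected for more than 20 hours, with
#' occasional partially affected days, mimicking agency qualifier data in
#' which short monitor outages shave hours off otherwise fully affected
#' days.  Defaults target roughly 150-220 smoke days over six years.
#'
#' @param n_days study length in days.
#' @param start_date first calendar day (ISO string or `Date`).
#' @param episode_rate expected number of smoke episodes per year.
#' @param episode_length_dist either a single number (every episode has
#'   exactly that many days) or a list with `meanlog`/`sdlog` of a
#'   lognormal episode-length distribution (rounded up to >= 1 day).
#' @param seed integer seed; all randomness is scoped to this call.
#' @return a data frame (class `wildfire_calendar`) with columns `date`,
#'   `smoke_hours` (0-24) and `wf_day` (logical).
#' @export
generate_wildfire_calendar <- function(n_days, start_date = "2013-01-01",
                                       episode_rate = 4,
                                       episode_length_dist =
                                         list(meanlog = log(5), sdlog = 0.9),
                                       seed = 1L) {
  n_days <- check_scalar_count(n_days, "n_days")
  if (episode_rate < 0) abort("episode_rate must be >= 0",
                              class = "smokegam_argument_error")
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  hours <- integer(n_days)
  withr::with_seed(seed, {
    n_years <- n_days / 365.25
    n_episodes <- rpois(1L, episode_rate * n_years)
    if (n_episodes > 0) {
      ## warm-season weighting of episode start days, peak mid August
      w <- exp(-((doy - 227) / 45)^2) + 0.02
      starts <- sample.int(n_days, n_episodes, replace = TRUE, prob = w)
      lens <- if (is.numeric(episode_length_dist) &&
                  length(episode_length_dist) == 1L) {
        rep(as.integer(episode_length_dist), n_episodes)
      } else {
        pmax(1L, as.integer(round(rlnorm(n_episodes,
                                         episode_length_dist$meanlog,
                                         episode_length_dist$sdlog))))
      }
      smoke <- logical(n_days)
      for (i in seq_len(n_episodes)) {
        idx <- starts[i]:min(n_days, starts[i] + lens[i] - 1L)
        smoke[idx] <- TRUE
      }
      ns <- sum(smoke)
      if (ns > 0) {
        u <- runif(ns)
        h <- ifelse(u < 0.85, 24L,
                    ifelse(u < 0.97, sample(21:23, ns, replace = TRUE),
                           sample(1:20, ns, replace = TRUE)))
        hours[smoke] <- as.integer(h)
      }
    }
  })
  structure(data.frame(date = dates, smoke_hours = hours,
                       wf_day = hours >= 1L),
            class = c("wildfire_calendar", "data.frame"))
}

#' Generate daily weather series
#'
#' Seasonal daily minimum/mean/maximum temperature with AR(1) weather
#' noise and mean relative humidity anticorrelated with temperature
#' (targets: overall mean temperature near 13 C, warm-season means near
#' 24 C, temperature-RH correlation around -0.8).
#'
#' @param n_days number of days.
#' @param start_date first calendar day.
#' @param seed integer seed.
#' @param mean_temp annual mean of daily mean temperature (C).
#' @param amplitude seasonal half-range of temperature (C); 0 plus
#'   `noise_sd = 0` yields a constant series.
#' @param noise_sd innovation SD of the AR(1) temperature noise.
#' @param rh_mean mean relative humidity (%).
#' @param rh_slope RH change per degree C (negative).
#' @param rh_noise_sd SD of independent RH noise.
#' @return data frame with `date`, `temp_min`, `temp_mean`, `temp_max`,
#'   `rh_mean`.
#' @export
generate_weather <- function(n_days, start_date = "2013-01-01", seed = 1L,
                             mean_temp = 13.3, amplitude = 11.5,
                             noise_sd = 3, rh_mean = 43, rh_slope = -1.5,
                             rh_noise_sd = 10) {
  n_days <- check_scalar_count(n_days, "n_days")
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  base <- mean_temp + amplitude * cos(2 * pi * (doy - 196) / 365.25)
  withr::with_seed(seed, {
    e <- numeric(n_days)
    if (noise_sd > 0) {
      rho <- 0.7
      innov <- rnorm(n_days, 0, noise_sd * sqrt(1 - rho^2))
      e[1] <- rnorm(1, 0, noise_sd)
      for (t in 2:max(2, n_days)) if (t <= n_days)
        e[t] <- rho * e[t - 1] + innov[t]
    }
    tmean <- base + e
    spread_lo <- 4.5 + abs(rnorm(n_days, 0, 1.5))
    spread_hi <- 5.5 + abs(rnorm(n_days, 0, 1.5))
    if (noise_sd == 0) spread_lo <- spread_hi <- rep(5, n_days)
    rh <- rh_mean + rh_slope * (tmean - mean_temp) +
      rnorm(n_days, 0, rh_noise_sd)
  })
  data.frame(date = dates, temp_min = tmean - spread_lo,
             temp_mean = tmean, temp_max = tmean + spread_hi,
             rh_mean = pmin(100, pmax(5, rh)))
}

#' Generate a multi-monitor PM panel
#'
#' Produces per-monitor daily PM2.5, PM10-2.5 and PM10 series with a
#' shared seasonal lognormal baseline (fine PM peaks in winter), wildfire
#' spikes applied predominantly to PM2.5 (a small additive bump on the
#' coarse fraction), `PM10 = PM2.5 + PM10-2.5` per monitor-day, staggered
#' monitor activity windows, sporadic per-fraction dropout, and a
#' patient-count weight per monitor.  Values outside a monitor's activity
#' window are missing.
#'
#' @param calendar a `wildfire_calendar`.
#' @param n_monitors number of monitors.
#' @param activity_windows list of length-2 integer vectors (first/last
#'   active day index) per monitor; `NULL` for staggered defaults with
#'   monitor 1 always active.
#' @param weights positive patient counts, one per monitor.
#' @param seed integer seed.
#' @param spike_scale multiplier on the wildfire PM2.5 spike (0 = no
#'   contamination).
#' @param coarse_bump additive ug/m3 added to PM10-2.5 on smoke days.
#' @param dropout_rate per-day probability a monitor-fraction reading is
#'   missing inside its activity window.
#' @return an object of class `monitor_panel`: list with `data` (long
#'   data frame: `monitor_id`, `date`, `fraction`, `value`, `active`),
#'   `monitors` (id, weight, radius_km) and `dates`.
#' @export
generate_monitor_panel <- function(calendar, n_monitors = 4,
                                   activity_windows = NULL,
                                   weights = c(21000, 8000, 13000, 3500),
                                   seed = 1L, spike_scale = 1,
                                   coarse_bump = 0.7,
                                   dropout_rate = 0.01) {
  stopifnot(inherits(calendar, "wildfire_calendar"))
  n_monitors <- check_scalar_count(n_monitors, "n_monitors")
  n <- nrow(calendar)
  if (is.null(activity_windows)) {
    activity_windows <- default_activity_windows(n, n_monitors)
  }
  if (length(weights) > n_monitors) weights <- weights[seq_len(n_monitors)]
  if (length(activity_windows) != n_monitors ||
      length(weights) != n_monitors)
    abort("need one activity window and one weight per monitor",
          class = "smokegam_argument_error")
  if (any(weights <= 0)) abort("monitor weights must be positive",
                               class = "smokegam_argument_error")
  doy <- as.integer(format(calendar$date, "%j"))
  smoke <- calendar$wf_day
  ids <- sprintf("M%02d", seq_len(n_monitors))
  rows <- withr::with_seed(seed, {
    ## shared regional fields (log scale), winter-peaking fine PM baseline;
    ## AR(1) day-to-day persistence emulates multi-day stagnation episodes
    ## (so non-wildfire rolling-average maxima are realistically heavy)
    ar1 <- function(n, rho, sd_marg) {
      e <- numeric(n)
      e[1] <- rnorm(1, 0, sd_marg)
      innov <- rnorm(n, 0, sd_marg * sqrt(1 - rho^2))
      for (t in seq_len(n)[-1]) e[t] <- rho * e[t - 1] + innov[t]
      e
    }
    base_fine <- log(6.2) + 0.35 * cos(2 * pi * (doy - 15) / 365.25) +
      ar1(n, 0.85, 0.45)
    base_coarse <- log(9.5) + 0.15 * cos(2 * pi * (doy - 200) / 365.25) +
      ar1(n, 0.7, 0.45)
    spike <- numeric(n)
    if (any(smoke))
      spike[smoke] <- spike_scale * rlnorm(sum(smoke), log(11), 0.6) *
        (calendar$smoke_hours[smoke] / 24)
    out <- vector("list", n_monitors)
    for (m in seq_len(n_monitors)) {
      w <- activity_windows[[m]]
      in_window <- seq_len(n) >= w[1] & seq_len(n) <= w[2]
      pm25 <- exp(base_fine + rnorm(n, 0, 0.25)) +
        spike * exp(rnorm(n, 0, 0.2))
      pmc <- exp(base_coarse + rnorm(n, 0, 0.30)) +
        ifelse(smoke, coarse_bump, 0)
      pm10 <- pm25 + pmc
      vals <- cbind(pm25 = pm25, pm_coarse = pmc, pm10 = pm10)
      frac_rows <- lapply(names(PM_FRACTIONS), function(f) {
        ## monitor 1 is the continuously active reference monitor (one
        ## monitor was active for the whole period for all fractions)
        drop <- if (m == 1L) rep(FALSE, n) else runif(n) < dropout_rate
        active <- in_window & !drop
        data.frame(monitor_id = ids[m], date = calendar$date,
                   fraction = f,
                   value = ifelse(active, vals[, f], NA_real_),
                   active = as.integer(active))
      })
      out[[m]] <- do.call(rbind, frac_rows)
    }
    do.call(rbind, out)
  })
  monitors <- data.frame(monitor_id = ids, weight = weights,
                         radius_km = c(5, rep(5, n_monitors - 1)))
  structure(list(data = rows, monitors = monitors, dates = calendar$date),
            class = "monitor_panel")
}

default_activity_windows <- function(n, n_monitors) {
  full <- c(1L, n)
  w <- list(full,
            c(as.integer(0.15 * n) + 1L, n),
            c(1L, as.integer(0.85 * n)),
            c(as.integer(0.40 * n) + 1L, n))
  if (n_monitors <= 4L) return(w[seq_len(n_monitors)])
  c(w, replicate(n_monitors - 4L, full, simplify = FALSE))
}

#' Generate negative-binomial daily visit counts
#'
#' Assembles the ground-truth linear predictor (calendar effects, smooth
#' long-term trend, 7-day mean temperature, autoregressive feedback on
#' previously generated counts via `log(1 + y)`, and the PM2.5 x wildfire
#' terms) day by day and draws NB counts.  The lag-0 weighted PM2.5
#' exposure must be available on every day.
#'
#' @param exposures an `exposure_panel` (see [build_exposure_panel()]).
#' @param weather data frame from [generate_weather()].
#' @param calendar a `wildfire_calendar`.
#' @param truth a [true_params()] object.
#' @param seed integer seed.
#' @param init_count pre-study count level used for the AR warm-up lags.
#' @return data frame with `date` and `visits`.
#' @export
generate_visits <- function(exposures, weather, calendar, truth,
                            seed = 1L, init_count = 8) {
  stopifnot(inherits(truth, "true_params"),
            inherits(exposures, "exposure_panel"))
  ed <- exposures$data
  if (!identical(ed$date, weather$date) ||
      !identical(ed$date, calendar$date))
    abort("exposures, weather and calendar must share one date index",
          class = "smokegam_argument_error")
  n <- nrow(ed)
  pm <- ed$pm25
  if (anyNA(pm))
    abort("missing lag-0 weighted PM2.5 on day(s) ",
          paste(head(which(is.na(pm)), 5), collapse = ", "),
          "; cannot generate visits",
          class = "smokegam_generation_error")
  wf <- as.numeric(calendar$wf_day)
  dow <- dow_indicators(ed$date)
  hol <- holiday_indicators(ed$date)
  ## trailing 7-day mean temperature with an expanding-window warm-up so
  ## the first week is defined for generation (fitted rows drop it anyway)
  temp7 <- rolling_mean(weather$temp_mean, 7L)
  for (t in 1:min(6L, n)) temp7[t] <- mean(weather$temp_mean[1:t])
  tt <- seq_len(n)
  trend <- truth$trend_amplitude *
    cos(2 * pi * (tt - truth$seasonal_phase) / truth$trend_period_days)
  eta_fixed <- truth$intercept +
    drop(dow %*% truth$dow_effects) +
    drop(hol %*% truth$holiday_effects) +
    trend + truth$temp_coef * temp7 +
    (truth$beta1_pm + truth$beta2_interaction * wf) *
      (pm / truth$pm_scale) +
    truth$beta3_wf * wf
  y <- integer(n)
  withr::with_seed(seed, {
    for (t in seq_len(n)) {
      arx <- vapply(1:10, function(j) {
        yl <- if (t - j >= 1) y[t - j] else init_count
        log1p(yl)
      }, numeric(1))
      eta <- eta_fixed[t] + sum(truth$ar_coefs * arx)
      mu <- exp(min(eta, 20))
      y[t] <- as.integer(rnbinom(1L, size = truth$nb_dispersion, mu = mu))
    }
  })
  data.frame(date = ed$date, visits = y)
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator: wildfire calendar, monitor panel, weather,
#' exposure panel (through the real exposure-construction code) and NB
#' visit counts with known truth.  Sub-seeds are derived deterministically
#' from `seed`.
#'
#' @param n_days study length (default 2192 days, six years 2013-2018).
#' @param seed master integer seed.
#' @param truth a [true_params()] object.
#' @param start_date first calendar day.
#' @param ... passed on to [generate_monitor_panel()].
#' @return list with `calendar`, `panel`, `weather`, `exposure`, `visits`,
#'   `truth`.
#' @export
simulate_study <- function(n_days = 2192, seed = 1L, truth = true_params(),
                           start_date = "2013-01-01", ...) {
  seed <- as.integer(seed)
  sub <- (seed * 13L + c(1L, 2L, 3L, 4L)) %% 2147483629L
  calendar <- generate_wildfire_calendar(n_days, start_date, seed = sub[1])
  panel <- generate_monitor_panel(calendar, seed = sub[2], ...)
  weather <- generate_weather(n_days, start_date, seed = sub[3])
  exposure <- build_exposure_panel(panel, calendar)
  visits <- generate_visits(exposure, weather, calendar, truth,
                            seed = sub[4])
  list(calendar = calendar, panel = panel, weather = weather,
       exposure = exposure, visits = visits, truth = truth)
}
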