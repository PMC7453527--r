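#' Classify days as wildfire days from hourly qualifier counts
#'
#' A day counts as a wildfire day if any hour of that day was flagged as
#' smoke-affected (no distinction is made between wildfire and
#' prescribed-burn smoke).
#'
#' @param qualifier_hours integer vector of smoke-affected hours per day,
#'   each in 0-24.
#' @return logical vector.
#' @examples
#' classify_wildfire_day(c(0, 1, 24))
#' @export
classify_wildfire_day <- function(qualifier_hours) {
  if (!all(is_wholenumber(qualifier_hours)) ||
      any(qualifier_hours < 0 | qualifier_hours > 24))
    abort("qualifier_hours must be integers in [0, 24]",
          class = "smokegam_argument_error")
  qualifier_hours >= 1
}

#' Construct a monitor panel
#'
#' Bundles long-format per-monitor PM measurements with the monitor
#' weight table.  Rows must be unique in (monitor, date, fraction);
#' values must be non-negative where present and `NA` where a monitor is
#' inactive.
#'
#' @param data data frame with columns `monitor_id`, `date` (`Date`),
#'   `fraction` (`"pm25"`, `"pm_coarse"`, `"pm10"`), `value` (ug/m3 or
#'   `NA`), `active` (0/1).
#' @param monitors data frame with `monitor_id`, `weight` (> 0, patient
#'   count) and optionally `radius_km`.
#' @param dates full daily date index; default: the range of `data$date`.
#' @return an object of class `monitor_panel`.
#' @export
monitor_panel <- function(data, monitors, dates = NULL) {
  require_columns(data, c("monitor_id", "date", "fraction", "value",
                          "active"), "monitor data")
  require_columns(monitors, c("monitor_id", "weight"), "monitor table")
  if (!all(data$fraction %in% names(PM_FRACTIONS)))
    abort("unknown fraction(s) in monitor data",
          class = "smokegam_argument_error")
  if (any(monitors$weight <= 0))
    abort("monitor weights must be positive",
          class = "smokegam_argument_error")
  if (anyDuplicated(paste(data$monitor_id, data$date, data$fraction)))
    abort("duplicate monitor-date-fraction rows",
          class = "smokegam_argument_error")
  if (any(data$value < 0, na.rm = TRUE))
    abort("PM values must be >= 0 where present",
          class = "smokegam_argument_error")
  if (!"radius_km" %in% names(monitors)) monitors$radius_km <- 5
  dates <- dates %||% seq(min(data$date), max(data$date), by = "day")
  structure(list(data = data, monitors = monitors, dates = dates),
            class = "monitor_panel")
}

#' Patient-count-weighted daily exposure
#'
#' Daily population exposure for one PM fraction: the weighted average of
#' the monitors active (and reporting) for that fraction on each day, with
#' weights renormalized daily over the active subset.  Missing when no
#' monitor is active.
#'
#' @param panel a `monitor_panel`.
#' @param fraction one of `"pm25"`, `"pm_coarse"`, `"pm10"`.
#' @param dates optional `Date` subset (default: all panel dates).
#' @return data frame with `date` and `value` (ug/m3, `NA` if no active
#'   monitor).
#' @export
weighted_daily_exposure <- function(panel, fraction, dates = NULL) {
  stopifnot(inherits(panel, "monitor_panel"))
  fraction <- check_fraction(fraction)
  dates <- dates %||% panel$dates
  d <- panel$data[panel$data$fraction == fraction, ]
  d <- merge(d, panel$monitors[, c("monitor_id", "weight")],
             by = "monitor_id")
  d <- d[d$active == 1L & !is.na(d$value), ]
  num <- tapply(d$value * d$weight, d$date, sum)
  den <- tapply(d$weight, d$date, sum)
  val <- as.numeric(num / den)
  names(val) <- names(num)
  data.frame(date = dates,
             value = unname(val[as.character(dates)]))
}

#' Rolling lag-set average
#'
#' Average of a daily series over a lag set: lag 0 (same day), lags 0-2
#' (same day plus two prior) or lags 0-6.  Any missing day inside the
#' window makes the average missing; the first `max(lag)` days are
#' undefined.
#'
#' @param series numeric daily values.
#' @param lag_set `"0"`, `"0-2"` or `"0-6"`.
#' @return numeric vector of the same length.
#' @export
rolling_lag_average <- function(series, lag_set) {
  lag_set <- check_lag_set(lag_set)
  rolling_mean(series, length(LAG_SETS[[lag_set]]))
}

#' Tri-state wildfire indicator over a lag set
#'
#' `1` if every day in the lag window is a wildfire day, `0` if none is,
#' and the sentinel [WF_EXCLUDED] (`-1`) for a mixture (such observations
#' are dropped from any model using this indicator).  Days whose window
#' extends before the series start are `NA`.
#'
#' @param wf_flags logical daily wildfire-day flags.
#' @param lag_set `"0"`, `"0-2"` or `"0-6"`.
#' @return integer vector with values 1, 0, -1 or `NA`.
#' @export
wildfire_lag_indicator <- function(wf_flags, lag_set) {
  lag_set <- check_lag_set(lag_set)
  k <- length(LAG_SETS[[lag_set]])
  s <- rolling_mean(as.numeric(wf_flags), k) * k
  out <- rep(WF_EXCLUDED, length(wf_flags))
  out[!is.na(s) & s == k] <- 1L
  out[!is.na(s) & s == 0] <- 0L
  out[is.na(s)] <- NA_integer_
  out
}

#' @rdname wildfire_lag_indicator
#' @format `WF_EXCLUDED` is the integer sentinel (-1) marking observations
#'   whose lag window mixes wildfire and non-wildfire days.
#' @export
WF_EXCLUDED <- -1L

#' Exceedance exclusion of high-PM2.5 wildfire observations
#'
#' Flags (for removal) wildfire observations whose lag-averaged PM2.5
#' strictly exceeds the maximum lag-averaged PM2.5 observed on
#' non-wildfire observations, so that wildfire and non-wildfire effects
#' are compared over overlapping concentration ranges.  The rule keys on
#' PM2.5 only, is applied separately per lag set, and the threshold is
#' computed over indicator-0 observations only.  Boundary equality
#' retains the day.
#'
#' @param pm25_lagavg lag-averaged weighted PM2.5 (ug/m3).
#' @param wf_indicator tri-state indicator from
#'   [wildfire_lag_indicator()], aligned with `pm25_lagavg`.
#' @return logical mask (`TRUE` = drop), with the non-wildfire maximum in
#'   attribute `"threshold"`.
#' @export
exceedance_exclusion <- function(pm25_lagavg, wf_indicator) {
  stopifnot(length(pm25_lagavg) == length(wf_indicator))
  ref <- pm25_lagavg[!is.na(wf_indicator) & wf_indicator == 0L]
  ref <- ref[is.finite(ref)]
  if (!length(ref))
    abort("no non-wildfire observations with PM2.5; exceedance threshold ",
          "undefined", class = "smokegam_configuration_error")
  thr <- max(ref)
  mask <- !is.na(wf_indicator) & wf_indicator == 1L &
    is.finite(pm25_lagavg) & pm25_lagavg > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Monitor-activity indicator columns
#'
#' One 0/1 column per monitor marking whether it was active for the given
#' fraction at any lag in the lag set (controls for shifts in the
#' composition of the weighted exposure when monitors come and go).
#'
#' @param panel a `monitor_panel`.
#' @param fraction PM fraction id.
#' @param lag_set lag-set id.
#' @return integer matrix, one row per panel date, one named column per
#'   monitor.
#' @export
monitor_activity_indicators <- function(panel, fraction, lag_set) {
  stopifnot(inherits(panel, "monitor_panel"))
  fraction <- check_fraction(fraction)
  lag_set <- check_lag_set(lag_set)
  lags <- LAG_SETS[[lag_set]]
  dates <- panel$dates
  d <- panel$data[panel$data$fraction == fraction, ]
  ids <- panel$monitors$monitor_id
  out <- vapply(ids, function(id) {
    a <- integer(length(dates))
    di <- d[d$monitor_id == id, ]
    a[match(di$date[di$active == 1L], dates)] <- 1L
    any_lag <- Reduce(`pmax`, lapply(lags, function(k) {
      c(rep(0L, k), a[seq_len(length(a) - k)])
    }))
    as.integer(any_lag)
  }, integer(length(dates)))
  colnames(out) <- ids
  out
}

#' Build the analysis-ready exposure panel
#'
#' Combines the weighted daily concentrations, lag-set rolling averages,
#' tri-state wildfire indicators, exceedance-exclusion masks and
#' monitor-activity indicators for every fraction and lag set.
#'
#' @param panel a `monitor_panel`.
#' @param calendar a `wildfire_calendar` on the same dates.
#' @param lag_sets lag-set ids to construct (default all three).
#' @return an object of class `exposure_panel`: list with `data` (one row
#'   per day: `date`, `smoke_hours`, `wf_day`, weighted `pm25` /
#'   `pm_coarse` / `pm10`, per-lag-set averages `<fraction>_l0` etc.,
#'   tri-state `wf_l0` etc., masks `excl_l0` etc.), `activity` (nested
#'   list `[[fraction]][[lag_set]]` of indicator matrices), `thresholds`
#'   (non-wildfire PM2.5 maxima per lag set) and `monitors`.
#' @export
build_exposure_panel <- function(panel, calendar,
                                 lag_sets = names(LAG_SETS)) {
  stopifnot(inherits(panel, "monitor_panel"),
            inherits(calendar, "wildfire_calendar"))
  if (!identical(panel$dates, calendar$date))
    abort("panel and calendar must share one date index",
          class = "smokegam_argument_error")
  lag_sets <- vapply(lag_sets, check_lag_set, character(1))
  df <- data.frame(date = calendar$date,
                   smoke_hours = calendar$smoke_hours,
                   wf_day = classify_wildfire_day(calendar$smoke_hours))
  for (f in names(PM_FRACTIONS))
    df[[f]] <- weighted_daily_exposure(panel, f)$value
  activity <- lapply(names(PM_FRACTIONS), function(f) {
    al <- lapply(lag_sets, function(ls)
      monitor_activity_indicators(panel, f, ls))
    names(al) <- lag_sets
    al
  })
  names(activity) <- names(PM_FRACTIONS)
  thresholds <- numeric(0)
  for (ls in lag_sets) {
    sfx <- lag_suffix(ls)
    for (f in names(PM_FRACTIONS))
      df[[paste0(f, "_", sfx)]] <- rolling_lag_average(df[[f]], ls)
    df[[paste0("wf_", sfx)]] <- wildfire_lag_indicator(df$wf_day, ls)
    m <- exceedance_exclusion(df[[paste0("pm25_", sfx)]],
                              df[[paste0("wf_", sfx)]])
    thresholds[ls] <- attr(m, "threshold")
    df[[paste0("excl_", sfx)]] <- as.logical(m)
  }
  structure(list(data = df, activity = activity, thresholds = thresholds,
                 monitors = panel$monitors, lag_sets = lag_sets),
            class = "exposure_panel")
}
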