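#' Holiday indicator variables
#'
#' Builds the 17 holiday indicator columns used as calendar covariates:
#' the 10 US federal holidays observed throughout 2013-2018 (New Year's
#' Day, Martin Luther King Jr. Day, Presidents' Day, Memorial Day,
#' Independence Day, Labor Day, Columbus Day, Veterans Day, Thanksgiving,
#' Christmas) plus Christmas Eve, New Year's Eve, the day after
#' Thanksgiving, Easter Sunday, Halloween, Cinco de Mayo and Super Bowl
#' Sunday (first Sunday of February).  Holidays are marked on their actual
#' calendar date, not a shifted observance date.
#'
#' @param dates a `Date` vector.
#' @return an integer 0/1 matrix with one named column per holiday and one
#'   row per date.
#' @examples
#' h <- holiday_indicators(as.Date(c("2013-07-04", "2013-07-05")))
#' h[, "independence_day"]
#' @export
holiday_indicators <- function(dates) {
  if (!inherits(dates, "Date")) abort("dates must be of class Date",
                                      class = "smokegam_argument_error")
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  sets <- holiday_dates(years)
  out <- vapply(sets, function(d) as.integer(dates %in% d),
                integer(length(dates)))
  if (length(dates) == 1L) out <- matrix(out, nrow = 1L,
                                         dimnames = list(NULL, names(sets)))
  out
}

HOLIDAY_NAMES <- c(
  "new_years_day", "mlk_day", "presidents_day", "memorial_day",
  "independence_day", "labor_day", "columbus_day", "veterans_day",
  "thanksgiving", "christmas", "christmas_eve", "new_years_eve",
  "day_after_thanksgiving", "easter", "halloween", "cinco_de_mayo",
  "super_bowl_sunday")

holiday_dates <- function(years) {
  thx <- vapply(years, nth_weekday, numeric(1), month = 11, wday = 4L, n = 3L)
  sets <- list(
    new_years_day   = as.Date(sprintf("%d-01-01", years)),
    mlk_day         = nth_weekday_dates(years, 1, 1L, 3L),
    presidents_day  = nth_weekday_dates(years, 2, 1L, 3L),
    memorial_day    = last_weekday_dates(years, 5, 1L),
    independence_day = as.Date(sprintf("%d-07-04", years)),
    labor_day       = nth_weekday_dates(years, 9, 1L, 1L),
    columbus_day    = nth_weekday_dates(years, 10, 1L, 2L),
    veterans_day    = as.Date(sprintf("%d-11-11", years)),
    thanksgiving    = nth_weekday_dates(years, 11, 4L, 4L),
    christmas       = as.Date(sprintf("%d-12-25", years)),
    christmas_eve   = as.Date(sprintf("%d-12-24", years)),
    new_years_eve   = as.Date(sprintf("%d-12-31", years)),
    day_after_thanksgiving = nth_weekday_dates(years, 11, 4L, 4L) + 1L,
    easter          = as.Date(vapply(years, easter_date, numeric(1)),
                              origin = "1970-01-01"),
    halloween       = as.Date(sprintf("%d-10-31", years)),
    cinco_de_mayo   = as.Date(sprintf("%d-05-05", years)),
    super_bowl_sunday = nth_weekday_dates(years, 2, 0L, 1L))
  sets[HOLIDAY_NAMES]
}

## n-th weekday (wday: 0 = Sunday .. 6 = Saturday) of a month, as numeric date
nth_weekday <- function(year, month, wday, n) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  first_wday <- as.POSIXlt(first)$wday
  offset <- (wday - first_wday) %% 7L
  as.numeric(first + offset + 7L * (n - 1L))
}

nth_weekday_dates <- function(years, month, wday, n) {
  as.Date(vapply(years, nth_weekday, numeric(1), month = month,
                 wday = wday, n = n), origin = "1970-01-01")
}

last_weekday_dates <- function(years, month, wday) {
  as.Date(vapply(years, function(y) {
    last <- as.Date(sprintf("%d-%02d-01", y, month + 1L)) - 1L
    last_wday <- as.POSIXlt(last)$wday
    as.numeric(last - (last_wday - wday) %% 7L)
  }, numeric(1)), origin = "1970-01-01")
}

## Gregorian Easter Sunday (anonymous computus), as numeric date
easter_date <- function(year) {
  a <- year %% 19; b <- year %/% 100; cc <- year %% 100
  d <- b %/% 4; e <- b %% 4; f <- (b + 8) %/% 25
  g <- (b - f + 1) %/% 3; h <- (19 * a + b - d - g + 15) %% 30
  i <- cc %/% 4; k <- cc %% 4
  l <- (32 + 2 * e + 2 * i - h - k) %% 7
  m <- (a + 11 * h + 22 * l) %/% 451
  month <- (h + l - 7 * m + 114) %/% 31
  day <- ((h + l - 7 * m + 114) %% 31) + 1
  as.numeric(as.Date(sprintf("%04d-%02d-%02d", year, month, day)))
}

## six day-of-week indicators, Sunday as the reference level
dow_indicators <- function(dates) {
  wd <- as.POSIXlt(dates)$wday  # 0 = Sunday
  lev <- 1:6
  out <- vapply(lev, function(l) as.integer(wd == l), integer(length(dates)))
  colnames(out) <- c("dow_mon", "dow_tue", "dow_wed", "dow_thu", "dow_fri",
                     "dow_sat")
  out
}
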