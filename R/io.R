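## CSV dialects: ISO-8601 dates, header rows, concentrations in ug/m3,
## counts as non-negative integers, missing values as empty fields.

parse_dates <- function(x, file) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (anyNA(d))
    abort("unparseable or missing date(s) in ", file, " at row(s) ",
          paste(head(if (length(bad)) bad else which(is.na(d)), 5),
                collapse = ", "),
          class = "smokegam_parse_error")
  d
}

require_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    abort("schema mismatch in ", file, ": missing column(s) ",
          paste(miss, collapse = ", "), class = "smokegam_parse_error")
}

#' Write / read the per-monitor PM concentration CSV
#'
#' Long format: `monitor_id, date, parameter (PM25 | PM10_25 | PM10),
#' value_ugm3, active`.  A companion weights CSV
#' (`monitor_id, weight, radius_km`) carries the patient-count weights.
#'
#' @param panel a `monitor_panel`.
#' @param path output CSV path.
#' @param weights_path path of the weights CSV.
#' @return `read_monitor_csv` returns a `monitor_panel`;
#'   the writers return their path invisibly.
#' @export
write_monitor_csv <- function(panel, path, weights_path) {
  stopifnot(inherits(panel, "monitor_panel"))
  d <- panel$data
  out <- data.frame(monitor_id = d$monitor_id,
                    date = format(d$date, "%Y-%m-%d"),
                    parameter = unname(PM_FRACTIONS[d$fraction]),
                    value_ugm3 = round(d$value, 4),
                    active = d$active)
  data.table::fwrite(out, path, na = "")
  data.table::fwrite(panel$monitors, weights_path, na = "")
  invisible(path)
}

#' @rdname write_monitor_csv
#' @export
read_monitor_csv <- function(path, weights_path) {
  d <- as.data.frame(data.table::fread(path, na.strings = ""))
  require_columns(d, c("monitor_id", "date", "parameter", "value_ugm3",
                       "active"), path)
  d$date <- parse_dates(d$date, path)
  codes <- stats::setNames(names(PM_FRACTIONS), PM_FRACTIONS)
  if (!all(d$parameter %in% names(codes)))
    abort("unknown parameter code(s) in ", path, ": ",
          paste(unique(setdiff(d$parameter, names(codes))), collapse = ", "),
          class = "smokegam_parse_error")
  key <- paste(d$monitor_id, d$date, d$parameter)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    abort("duplicate monitor-date rows in ", path, " at row(s) ",
          paste(head(dup, 10), collapse = ", "),
          class = "smokegam_parse_error")
  }
  if (any(d$value_ugm3 < 0, na.rm = TRUE))
    abort("negative concentration(s) in ", path, " at row(s) ",
          paste(head(which(d$value_ugm3 < 0), 5), collapse = ", "),
          class = "smokegam_parse_error")
  w <- as.data.frame(data.table::fread(weights_path, na.strings = ""))
  require_columns(w, c("monitor_id", "weight"), weights_path)
  if (!"radius_km" %in% names(w)) w$radius_km <- 5
  if (any(w$weight <= 0))
    abort("non-positive monitor weight(s) in ", weights_path,
          class = "smokegam_parse_error")
  dates <- seq(min(d$date), max(d$date), by = "day")
  data_long <- data.frame(monitor_id = d$monitor_id, date = d$date,
                          fraction = codes[d$parameter],
                          value = d$value_ugm3,
                          active = as.integer(d$active))
  rownames(data_long) <- NULL
  monitor_panel(data_long, w[order(w$monitor_id), ], dates)
}

#' Write / read the hourly smoke-qualifier CSV
#'
#' One row per smoke-affected hour: `monitor_id, date, hour (0-23),
#' smoke_flag`.  The reader aggregates flagged hours to a daily
#' [wildfire_calendar] over the supplied date index (days with no rows
#' have zero smoke hours).
#'
#' @param calendar a `wildfire_calendar`.
#' @param path CSV path.
#' @param monitor_id qualifier monitor id (the downtown reference
#'   monitor).
#' @param dates full daily `Date` index for the reader.
#' @export
write_qualifier_csv <- function(calendar, path, monitor_id = "REF01") {
  stopifnot(inherits(calendar, "wildfire_calendar"))
  idx <- which(calendar$smoke_hours > 0)
  rows <- lapply(idx, function(i)
    data.frame(monitor_id = monitor_id,
               date = format(calendar$date[i], "%Y-%m-%d"),
               hour = seq_len(calendar$smoke_hours[i]) - 1L,
               smoke_flag = 1L))
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(monitor_id = character(), date = character(),
                         hour = integer(), smoke_flag = integer())
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_qualifier_csv
#' @export
read_qualifier_csv <- function(path, dates, monitor_id = NULL) {
  d <- as.data.frame(data.table::fread(path, na.strings = ""))
  require_columns(d, c("monitor_id", "date", "hour", "smoke_flag"), path)
  if (nrow(d)) {
    d$date <- parse_dates(d$date, path)
    if (any(d$hour < 0 | d$hour > 23))
      abort("hour out of range in ", path, class = "smokegam_parse_error")
    if (!is.null(monitor_id)) d <- d[d$monitor_id == monitor_id, ]
  }
  hours <- integer(length(dates))
  if (nrow(d)) {
    agg <- tapply(d$smoke_flag, d$date, function(x) sum(x > 0))
    m <- match(names(agg), as.character(dates))
    if (anyNA(m))
      abort("qualifier dates outside the study date index in ", path,
            class = "smokegam_parse_error")
    hours[m] <- as.integer(agg)
  }
  structure(data.frame(date = dates, smoke_hours = pmin(hours, 24L),
                       wf_day = hours >= 1L),
            class = c("wildfire_calendar", "data.frame"))
}

#' Write / read the daily weather CSV
#'
#' Columns `date, temp_min, temp_mean, temp_max, rh_mean`; the reader
#' requires a complete daily sequence and `min <= mean <= max`.
#'
#' @param weather weather data frame.
#' @param path CSV path.
#' @export
write_weather_csv <- function(weather, path) {
  out <- weather
  out$date <- format(out$date, "%Y-%m-%d")
  out[-1] <- lapply(out[-1], round, digits = 4)
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path, na.strings = ""))
  require_columns(d, c("date", "temp_min", "temp_mean", "temp_max",
                       "rh_mean"), path)
  d$date <- parse_dates(d$date, path)
  if (any(diff(as.integer(d$date)) != 1L))
    abort("weather dates must form a complete daily sequence in ", path,
          class = "smokegam_parse_error")
  bad <- which(d$temp_min > d$temp_mean | d$temp_mean > d$temp_max)
  if (length(bad))
    abort("temperature ordering min <= mean <= max violated in ", path,
          " at row(s) ", paste(head(bad, 5), collapse = ", "),
          class = "smokegam_parse_error")
  d
}

#' Write / read the daily visit-count CSV
#'
#' Columns `date, visits`; counts must be non-negative integers on a
#' complete daily sequence.
#'
#' @param visits data frame with `date` and `visits`.
#' @param path CSV path.
#' @export
write_visits_csv <- function(visits, path) {
  out <- data.frame(date = format(visits$date, "%Y-%m-%d"),
                    visits = visits$visits)
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_visits_csv
#' @export
read_visits_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path, na.strings = ""))
  require_columns(d, c("date", "visits"), path)
  d$date <- parse_dates(d$date, path)
  bad <- which(is.na(d$visits) | d$visits < 0 |
                 !is_wholenumber(d$visits))
  if (length(bad))
    abort("invalid visit count(s) in ", path, " at row(s) ",
          paste(head(bad, 5), collapse = ", "),
          " (counts must be non-negative integers)",
          class = "smokegam_parse_error")
  if (anyDuplicated(d$date))
    abort("duplicate dates in ", path, class = "smokegam_parse_error")
  if (any(diff(as.integer(d$date)) != 1L))
    abort("visit dates must form a complete daily sequence in ", path,
          class = "smokegam_parse_error")
  d$visits <- as.integer(d$visits)
  d
}

#' Read and validate a run configuration (JSON)
#'
#' A config names either real input files (`paths`: monitor, weights,
#' qualifier, weather, visits CSVs) or a `synthetic` generation block
#' (`n_days`, optional generator/truth overrides) -- exactly one of the
#' two -- plus optional `seed`, `output_dir`, `models` and `sensitivity`
#' blocks.
#'
#' @param path JSON file path, or an already-parsed list.
#' @return validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = TRUE) else path
  has_paths <- !is.null(cfg$paths)
  has_synth <- !is.null(cfg$synthetic)
  if (has_paths == has_synth)
    abort("config must contain exactly one of 'paths' or 'synthetic'",
          class = "smokegam_config_error")
  if (has_paths)
    for (k in c("monitor", "weights", "qualifier", "weather", "visits"))
      if (is.null(cfg$paths[[k]]))
        abort("config paths block missing '", k, "'",
              class = "smokegam_config_error")
  if (has_synth && is.null(cfg$synthetic$n_days))
    abort("synthetic block must give n_days",
          class = "smokegam_config_error")
  structure(cfg, class = c("run_config", "list"))
}

#' Load and validate the study tables named by a config
#'
#' For a `paths` config, parses and date-aligns the four inputs; the
#' synthetic branch is handled by [run_pipeline()] (which writes the
#' generated CSVs and re-reads them through these parsers).
#'
#' @param config a `run_config` with a `paths` block.
#' @return list with `panel` (`monitor_panel`), `weather`, `visits`,
#'   `calendar` (`wildfire_calendar`), all on one date index.
#' @export
load_study_tables <- function(config) {
  if (is.null(config$paths))
    abort("load_study_tables needs a config with a 'paths' block",
          class = "smokegam_config_error")
  p <- config$paths
  panel <- read_monitor_csv(p$monitor, p$weights)
  weather <- read_weather_csv(p$weather)
  visits <- read_visits_csv(p$visits)
  dates <- panel$dates
  if (!identical(weather$date, dates) || !identical(visits$date, dates))
    abort("monitor, weather and visit tables do not share one date index",
          class = "smokegam_parse_error")
  calendar <- read_qualifier_csv(p$qualifier, dates,
                                 monitor_id = config$qualifier_monitor)
  list(panel = panel, weather = weather, visits = visits,
       calendar = calendar)
}
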