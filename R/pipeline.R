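#' Run the full analysis pipeline
#'
#' Executes the pipeline stages -- data (load or synthesize, writing and
#' re-reading CSVs through the real parsers), exposure construction, the
#' model grid (nine single-fraction fits plus the two-fraction model),
#' derived inference (grid report and percent-increase surface) and the
#' meteorological sensitivity analyses -- writing all artifacts and a
#' deterministic machine-readable `summary.json` under `outdir`.  Any
#' stage error aborts with the stage name; artifacts written so far are
#' kept.
#'
#' @param config a `run_config`, a path to a JSON config, or `NULL` for
#'   the default synthetic demonstration config.
#' @param outdir output directory (overrides `config$output_dir`).
#' @param seed integer seed (overrides `config$seed`).
#' @param stages which stages to run (prefix of the full sequence).
#' @param verbose print progress.
#' @return the output directory, invisibly; the summary is in
#'   `summary.json`, a timestamped log in `log.txt`.
#' @export
run_pipeline <- function(config = NULL, outdir = NULL, seed = NULL,
                         stages = c("data", "exposure", "fit",
                                    "inference", "sensitivity"),
                         verbose = FALSE) {
  cfg <- read_run_config(config %||% default_synthetic_config())
  outdir <- outdir %||% cfg$output_dir %||%
    abort("no output directory given", class = "smokegam_config_error")
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(file.path(outdir, "data"), recursive = TRUE,
             showWarnings = FALSE)
  logf <- file.path(outdir, "log.txt")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      abort("pipeline stage '", name, "' failed: ", conditionMessage(e),
            class = "smokegam_pipeline_error")
    })
  }
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                               digits = NA, null = "null")
  log_line("smokegam ", as.character(utils::packageVersion("smokegam")),
           " | R ", R.version.string, " | seed ", seed,
           " | config hash ", sum(utf8ToInt(cfg_json)) %% 1000000L)
  summary <- list(seed = seed, config = jsonlite::fromJSON(cfg_json))

  tables <- stage("data", {
    if (!is.null(cfg$synthetic)) {
      sy <- cfg$synthetic
      truth <- do.call(true_params, sy$truth %||% list())
      sim <- simulate_study(n_days = sy$n_days, seed = seed,
                            truth = truth,
                            start_date = sy$start_date %||% "2013-01-01")
      dpath <- function(f) file.path(outdir, "data", f)
      write_monitor_csv(sim$panel, dpath("monitors.csv"),
                        dpath("weights.csv"))
      write_qualifier_csv(sim$calendar, dpath("qualifiers.csv"))
      write_weather_csv(sim$weather, dpath("weather.csv"))
      write_visits_csv(sim$visits, dpath("visits.csv"))
      cfg2 <- cfg
      cfg2$synthetic <- NULL
      cfg2$paths <- list(monitor = dpath("monitors.csv"),
                         weights = dpath("weights.csv"),
                         qualifier = dpath("qualifiers.csv"),
                         weather = dpath("weather.csv"),
                         visits = dpath("visits.csv"))
      load_study_tables(read_run_config(cfg2))
    } else load_study_tables(cfg)
  })
  summary$n_days <- length(tables$panel$dates)
  summary$wildfire_days <- sum(tables$calendar$wf_day)
  if (length(stages) == 1L && stages == "data") {
    write_summary(summary, outdir); return(invisible(outdir))
  }

  exposure <- stage("exposure", {
    ep <- build_exposure_panel(tables$panel, tables$calendar)
    data.table::fwrite(ep$data, file.path(outdir, "exposure.csv"),
                       na = "")
    ep
  })
  summary$exceedance_thresholds <- as.list(exposure$thresholds)
  summary$wf_indicator_counts <- lapply(exposure$lag_sets, function(ls)
    sum(exposure$data[[paste0("wf_", lag_suffix(ls))]] == 1L,
        na.rm = TRUE))
  names(summary$wf_indicator_counts) <- exposure$lag_sets
  if (!"fit" %in% stages) {
    write_summary(summary, outdir); return(invisible(outdir))
  }

  fits <- stage("fit", {
    study <- build_study_panel(exposure, tables$weather, tables$visits)
    specs <- pipeline_model_specs(cfg)
    ctl <- as.list(cfg$fit_control %||% list())
    labels <- vapply(specs, function(sp)
      if (sp$type == "two_fraction") "two_fraction"
      else paste0(sp$fraction, ":", sp$lag_set), character(1))
    ## an inestimable model (e.g. no qualifying wildfire runs for a lag
    ## set on a short series) leaves a gap in the grid, not an abort
    fits <- lapply(seq_along(specs), function(i)
      tryCatch(fit_nb_gam(assemble_design(study, specs[[i]]),
                          control = ctl),
               error = function(e) {
                 log_line("model ", labels[i], " not fitted: ",
                          conditionMessage(e))
                 NULL
               }))
    names(fits) <- labels
    write_fit_artifacts(fits[!vapply(fits, is.null, logical(1))],
                        file.path(outdir, "fits.json"))
    attr(fits, "study") <- study
    fits
  })
  summary$models <- lapply(fits, function(f)
    if (is.null(f)) list(fitted = FALSE)
    else list(deviance = f$deviance, nb_dispersion = f$nb_dispersion,
              spline_edf = f$spline_edf,
              smoothing_parameter = f$smoothing_parameter))
  if (!"inference" %in% stages) {
    write_summary(summary, outdir); return(invisible(outdir))
  }

  infer <- stage("inference", {
    single <- fits[names(fits) != "two_fraction"]
    report <- model_grid_report(single)
    data.table::fwrite(report, file.path(outdir, "model_grid.csv"),
                       na = "")
    wfpts <- retained_wildfire_points(exposure)
    surface <- evaluate_two_fraction_surface(fits[["two_fraction"]],
                                             wfpts)
    data.table::fwrite(surface, file.path(outdir, "surface.csv"),
                       na = "")
    list(report = report, surface = surface)
  })
  summary$model_grid <- lapply(seq_len(nrow(infer$report)), function(i)
    as.list(infer$report[i, c("fraction", "lag_set", "rr_nonwf", "rr_wf",
                              "factor", "percent", "p_value")]))
  summary$surface_significant_cells <-
    sum(infer$surface$significant, na.rm = TRUE)
  if (!"sensitivity" %in% stages) {
    write_summary(summary, outdir); return(invisible(outdir))
  }

  sens <- stage("sensitivity", {
    study <- attr(fits, "study")
    specs <- pipeline_model_specs(cfg, sensitivity = TRUE)
    specs <- Filter(function(sp) sp$type == "single", specs)
    out <- run_variants(study, specs,
                        control = as.list(cfg$fit_control %||% list()))
    data.table::fwrite(out, file.path(outdir, "sensitivity.csv"),
                       na = "")
    out
  })
  summary$sensitivity <- lapply(seq_len(nrow(sens)), function(i)
    as.list(sens[i, c("variant", "fraction", "lag_set", "percent",
                      "delta_percent")]))
  write_summary(summary, outdir)
  log_line("pipeline complete")
  invisible(outdir)
}

write_summary <- function(summary, outdir) {
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

## default model grid: 3 fractions x 3 lag sets + the two-fraction model
pipeline_model_specs <- function(cfg, sensitivity = FALSE) {
  base <- list(temp_metric = "mean", include_rh = FALSE, pm_scale = 5,
               spline_basis_size = 10)
  base <- modifyList(base, as.list(cfg$models %||% list()))
  lag_sets <- base$lag_sets %||% names(LAG_SETS)
  fractions <- base$fractions %||% names(PM_FRACTIONS)
  if (sensitivity) {
    sel <- cfg$sensitivity$models %||% "lag0"
    if (identical(sel, "lag0")) lag_sets <- "0"
  }
  mk <- function(...) model_spec(temp_metric = base$temp_metric,
                                 include_rh = base$include_rh,
                                 pm_scale = base$pm_scale,
                                 spline_basis_size = base$spline_basis_size,
                                 ...)
  specs <- list()
  for (f in fractions)
    for (ls in lag_sets)
      specs <- c(specs, list(mk(type = "single", fraction = f,
                                lag_set = ls)))
  if (!sensitivity) specs <- c(specs, list(mk(type = "two_fraction")))
  specs
}

## retained wildfire (lag-0) observations in the (PM2.5, PM10-2.5) plane
retained_wildfire_points <- function(exposure) {
  d <- exposure$data
  keep <- !is.na(d$wf_l0) & d$wf_l0 == 1L & !d$excl_l0 &
    !is.na(d$pm25_l0) & !is.na(d$pm_coarse_l0)
  data.frame(pm25 = d$pm25_l0[keep], pm_coarse = d$pm_coarse_l0[keep])
}

write_fit_artifacts <- function(fits, path) {
  art <- lapply(fits, function(f) list(
    spec = unclass(f$spec), coefficients = as.list(f$coefficients),
    covariance = unname(f$cov), smoothing_parameter = f$smoothing_parameter,
    spline_edf = f$spline_edf, nb_dispersion = f$nb_dispersion,
    deviance = f$deviance, converged = f$converged,
    dropped_columns = f$dropped))
  jsonlite::write_json(art, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

default_synthetic_config <- function(n_days = 450, seed = 1L) {
  list(synthetic = list(n_days = n_days), seed = seed,
       sensitivity = list(models = "lag0"))
}
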