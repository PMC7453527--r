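#' Sensitivity-analysis variants
#'
#' The primary analysis controls for a rolling 7-day average of daily
#' mean temperature without RH; the three alternatives replace the mean
#' with the daily minimum or maximum, or add a rolling 7-day mean RH.
#'
#' @return data frame with `label`, `temp_metric`, `include_rh`; the
#'   primary variant is the first row.
#' @export
sensitivity_variants <- function() {
  data.frame(label = c("primary", "min_temp", "max_temp", "mean_temp_rh"),
             temp_metric = c("mean", "min", "max", "mean"),
             include_rh = c(FALSE, FALSE, FALSE, TRUE))
}

#' Re-run models under alternative meteorological controls
#'
#' Refits each requested model spec once per variant (swapping the
#' temperature metric and the RH control) and tabulates the wildfire
#' modification estimates side by side, with deltas relative to the
#' primary variant.  The primary variant always comes first.
#'
#' @param study a `study_panel` (must carry all three temperature metrics
#'   and RH).
#' @param specs list of `model_spec`s to refit (their
#'   `temp_metric`/`include_rh` are overridden per variant).
#' @param variants data frame as returned by [sensitivity_variants()].
#' @param level confidence level.
#' @param control fitting control passed to [fit_nb_gam()].
#' @return data frame of class `sensitivity_report`: variant columns plus
#'   the [model_grid_report()] columns and `delta_percent` (modification
#'   percent minus the primary variant's, per model).
#' @export
run_variants <- function(study, specs, variants = sensitivity_variants(),
                         level = 0.95, control = list()) {
  stopifnot(inherits(study, "study_panel"))
  if (inherits(specs, "model_spec")) specs <- list(specs)
  need <- unique(paste0("temp7_", variants$temp_metric))
  if (any(variants$include_rh)) need <- c(need, "rh7")
  missing_cols <- setdiff(need, names(study$data))
  if (length(missing_cols))
    abort("study panel lacks weather column(s): ",
          paste(missing_cols, collapse = ", "),
          class = "smokegam_argument_error")
  if (!"primary" %in% variants$label)
    variants <- rbind(sensitivity_variants()[1, ], variants)
  variants <- variants[order(variants$label != "primary"), ]
  out <- list()
  for (v in seq_len(nrow(variants))) {
    fits <- lapply(specs, function(sp) {
      sp$temp_metric <- variants$temp_metric[v]
      sp$include_rh <- variants$include_rh[v]
      fit_nb_gam(assemble_design(study, sp), control = control)
    })
    names(fits) <- vapply(specs, function(sp)
      paste0(sp$fraction, ":", sp$lag_set), character(1))
    rep_v <- model_grid_report(fits, level)
    rep_v <- cbind(variant = variants$label[v],
                   temp_metric = variants$temp_metric[v],
                   include_rh = variants$include_rh[v], rep_v)
    out[[v]] <- rep_v
  }
  res <- do.call(rbind, out)
  prim <- res[res$variant == "primary", ]
  key <- paste(res$fraction, res$lag_set)
  pkey <- paste(prim$fraction, prim$lag_set)
  res$delta_percent <- res$percent - prim$percent[match(key, pkey)]
  rownames(res) <- NULL
  class(res) <- c("sensitivity_report", "data.frame")
  res
}
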