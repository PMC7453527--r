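#' Variance of a linear combination of coefficients
#'
#' `Var(w' b) = w' Sigma w`, the delta-method variance used for every
#' derived quantity (wildfire-day rate ratios, the two-fraction surface).
#'
#' @param covariance symmetric positive-semidefinite coefficient
#'   covariance matrix.
#' @param weights numeric vector, one weight per coefficient.
#' @return the scalar variance.
#' @examples
#' linear_combination_variance(matrix(c(1, .5, .5, 1), 2), c(1, 1))  # 3
#' @export
linear_combination_variance <- function(covariance, weights) {
  covariance <- as.matrix(covariance)
  if (length(weights) != ncol(covariance) ||
      nrow(covariance) != ncol(covariance))
    abort("weights length must equal the coefficient count",
          class = "smokegam_argument_error")
  if (max(abs(covariance - t(covariance))) >
      1e-8 * max(1, max(abs(covariance))))
    abort("covariance must be symmetric",
          class = "smokegam_argument_error")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    abort("covariance is not positive semidefinite",
          class = "smokegam_argument_error")
  drop(crossprod(weights, covariance %*% weights))
}

#' Percent-change / rate-ratio-factor conversions
#'
#' A multiplicative factor `f` on the rate scale corresponds to a
#' `(f - 1) * 100` percent change; the two functions are exact inverses.
#'
#' @param factor multiplicative rate-ratio factor.
#' @param percent percent change.
#' @return numeric.
#' @examples
#' percent_from_factor(1.028)  # 2.8
#' @export
percent_from_factor <- function(factor) (factor - 1) * 100

#' @rdname percent_from_factor
#' @export
factor_from_percent <- function(percent) percent / 100 + 1

#' Build a contrast result on the log-rate scale
#'
#' Packages a point estimate and standard error into the rate-ratio
#' representation with a two-sided Wald confidence interval (exponentiated
#' log-scale endpoints) and p-value.
#'
#' @param estimate log-rate estimate.
#' @param se standard error.
#' @param level confidence level.
#' @return object of class `contrast_result`: `estimate`, `se`,
#'   `rate_ratio`, `ci_low`, `ci_high` (rate-ratio scale),
#'   `percent_change`, `p_value`.
#' @export
contrast_result <- function(estimate, se, level = 0.95) {
  if (se < 0) abort("se must be >= 0", class = "smokegam_argument_error")
  zq <- qnorm(1 - (1 - level) / 2)
  rr <- exp(estimate)
  p <- if (se > 0) 2 * pnorm(-abs(estimate / se))
       else as.numeric(estimate != 0) * 0 + (estimate == 0) * 1
  structure(list(estimate = estimate, se = se, rate_ratio = rr,
                 ci_low = exp(estimate - zq * se),
                 ci_high = exp(estimate + zq * se),
                 percent_change = percent_from_factor(rr),
                 p_value = p, level = level),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("rate ratio %.4f (%.0f%% CI %.4f-%.4f), %+.2f%%, p = %.3g\n",
              x$rate_ratio, 100 * x$level, x$ci_low, x$ci_high,
              x$percent_change, x$p_value))
  invisible(x)
}

coef_index <- function(fit, role) {
  i <- which(fit$roles == role)
  if (length(i) != 1L)
    abort("fit does not contain exactly one '", role, "' coefficient",
          class = "smokegam_inference_error")
  i
}

#' Wildfire modification of the PM rate ratio
#'
#' From a single-fraction fit, returns the non-wildfire rate ratio
#' `exp(b1)`, the wildfire-day rate ratio `exp(b1 + b2)` (variance by the
#' linear-combination formula) and the modification factor `exp(b2)` --
#' the multiplicative change in the PM rate ratio when wildfire smoke is
#' present, also expressed as a percent.
#'
#' @param fit a `gam_fit` from a single-fraction model.
#' @param level confidence level.
#' @return list of class `wildfire_modification` with `non_wildfire`,
#'   `wildfire` and `modification` ([contrast_result()]s).
#' @export
wildfire_modification <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gam_fit"))
  i1 <- coef_index(fit, "pm")
  i2 <- coef_index(fit, "pm_wf")
  b <- fit$coefficients
  V <- fit$cov
  w <- rep(0, length(b)); w[c(i1, i2)] <- 1
  structure(list(
    non_wildfire = contrast_result(b[[i1]], sqrt(V[i1, i1]), level),
    wildfire = contrast_result(b[[i1]] + b[[i2]],
                               sqrt(linear_combination_variance(V, w)),
                               level),
    modification = contrast_result(b[[i2]], sqrt(V[i2, i2]), level)),
    class = "wildfire_modification")
}

#' Percent increase in visits due to wildfire smoke (two-fraction model)
#'
#' The closed-form surface value
#' `(exp(b2 * PM2.5/s + b4 * PM10-2.5/s + b5) - 1) * 100`, with PM in
#' ug/m3 and coefficients per `s` ug/m3 (default 5).
#'
#' @param beta2 PM2.5 x wildfire interaction coefficient (per `pm_scale`
#'   ug/m3).
#' @param beta4 PM10-2.5 x wildfire interaction coefficient.
#' @param beta5 wildfire main-effect coefficient.
#' @param pm25,pm_coarse concentrations in ug/m3 (vectorized).
#' @param pm_scale ug/m3 per coefficient unit.
#' @return percent increase(s).
#' @examples
#' two_fraction_percent(0.0747, 0.0341, -0.2259, 20, 15)  # ~19.1
#' @export
two_fraction_percent <- function(beta2, beta4, beta5, pm25, pm_coarse,
                                 pm_scale = 5) {
  percent_from_factor(exp(beta2 * pm25 / pm_scale +
                            beta4 * pm_coarse / pm_scale + beta5))
}

#' Evaluate the two-fraction percent-increase surface
#'
#' Evaluates the percent increase in visits attributable to wildfire
#' smoke on a (PM2.5, PM10-2.5) grid, with per-cell Wald p-values from
#' the linear-combination variance
#' `Var(b2 PM2.5 + b4 PM10-2.5 + b5)` and a support mask restricting
#' estimates to cells within `support_radius` ug/m3 (Euclidean, raw
#' concentration plane) of an observed wildfire point.
#'
#' @param fit a `gam_fit` from the two-fraction model.
#' @param wildfire_points data frame with columns `pm25` and `pm_coarse`
#'   (ug/m3): the retained wildfire observations.
#' @param pm25_grid,pm_coarse_grid grid axis values in ug/m3; default: a
#'   grid at `resolution` covering the wildfire points padded by the
#'   support radius.
#' @param resolution default grid step, ug/m3.
#' @param support_radius support distance in ug/m3.
#' @param level confidence level for significance (p < 1 - level).
#' @return data frame of class `surface_grid`: `pm25`, `pm_coarse`,
#'   `percent`, `se`, `p_value`, `in_support`, `significant`; cells
#'   outside support carry `NA` estimates.
#' @export
evaluate_two_fraction_surface <- function(fit, wildfire_points,
                                          pm25_grid = NULL,
                                          pm_coarse_grid = NULL,
                                          resolution = 0.5,
                                          support_radius = 5,
                                          level = 0.95) {
  stopifnot(inherits(fit, "gam_fit"))
  if (is.null(wildfire_points) || nrow(wildfire_points) == 0L)
    abort("empty wildfire observation set; surface support is undefined",
          class = "smokegam_inference_error")
  i2 <- coef_index(fit, "pm25_wf")
  i4 <- coef_index(fit, "pm_coarse_wf")
  i5 <- coef_index(fit, "wf")
  pm_scale <- if (!is.null(fit$spec)) fit$spec$pm_scale else 5
  if (is.null(pm25_grid))
    pm25_grid <- seq(max(0, floor(min(wildfire_points$pm25)) -
                           support_radius),
                     ceiling(max(wildfire_points$pm25)) + support_radius,
                     by = resolution)
  if (is.null(pm_coarse_grid))
    pm_coarse_grid <- seq(max(0, floor(min(wildfire_points$pm_coarse)) -
                                support_radius),
                          ceiling(max(wildfire_points$pm_coarse)) +
                            support_radius,
                          by = resolution)
  g <- expand.grid(pm25 = pm25_grid, pm_coarse = pm_coarse_grid,
                   KEEP.OUT.ATTRS = FALSE)
  b <- fit$coefficients
  V <- fit$cov[c(i2, i4, i5), c(i2, i4, i5)]
  x2 <- g$pm25 / pm_scale
  x4 <- g$pm_coarse / pm_scale
  est <- b[[i2]] * x2 + b[[i4]] * x4 + b[[i5]]
  se <- sqrt(x2^2 * V[1, 1] + x4^2 * V[2, 2] + V[3, 3] +
               2 * x2 * x4 * V[1, 2] + 2 * x2 * V[1, 3] +
               2 * x4 * V[2, 3])
  p <- 2 * pnorm(-abs(est / se))
  d2 <- outer(g$pm25, wildfire_points$pm25, `-`)^2 +
    outer(g$pm_coarse, wildfire_points$pm_coarse, `-`)^2
  in_support <- sqrt(apply(d2, 1, min)) <= support_radius
  out <- data.frame(pm25 = g$pm25, pm_coarse = g$pm_coarse,
                    percent = ifelse(in_support,
                                     percent_from_factor(exp(est)), NA),
                    se = ifelse(in_support, se, NA),
                    p_value = ifelse(in_support, p, NA),
                    in_support = in_support,
                    significant = in_support & p < (1 - level))
  class(out) <- c("surface_grid", "data.frame")
  out
}

#' Tabular report over a grid of single-fraction fits
#'
#' One row per model: non-wildfire rate ratio and CI, wildfire-day rate
#' ratio and CI, modification factor with CI and percent form, and a
#' significance flag at p < 0.05.  Failed/missing fits produce gaps with
#' a warning.
#'
#' @param fits named list of `gam_fit` objects (or `NULL` entries for
#'   failed fits); names like `"pm25:0-2"` are used as labels when the
#'   fit carries no spec.
#' @param level confidence level.
#' @return data frame of class `model_grid_report`.
#' @export
model_grid_report <- function(fits, level = 0.95) {
  if (inherits(fits, "gam_fit")) fits <- list(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    lab <- names(fits)[i] %||% as.character(i)
    if (is.null(f)) {
      warning("model ", lab, " missing from grid; reporting gap")
      return(data.frame(fraction = NA, lag_set = NA, rr_nonwf = NA,
                        rr_nonwf_lo = NA, rr_nonwf_hi = NA, rr_wf = NA,
                        rr_wf_lo = NA, rr_wf_hi = NA, factor = NA,
                        factor_lo = NA, factor_hi = NA, percent = NA,
                        p_value = NA, significant = NA))
    }
    m <- wildfire_modification(f, level)
    data.frame(
      fraction = f$spec$fraction %||% lab,
      lag_set = f$spec$lag_set %||% NA_character_,
      rr_nonwf = m$non_wildfire$rate_ratio,
      rr_nonwf_lo = m$non_wildfire$ci_low,
      rr_nonwf_hi = m$non_wildfire$ci_high,
      rr_wf = m$wildfire$rate_ratio,
      rr_wf_lo = m$wildfire$ci_low, rr_wf_hi = m$wildfire$ci_high,
      factor = m$modification$rate_ratio,
      factor_lo = m$modification$ci_low,
      factor_hi = m$modification$ci_high,
      percent = m$modification$percent_change,
      p_value = m$modification$p_value,
      significant = m$modification$p_value < (1 - level))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_grid_report", "data.frame")
  out
}
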