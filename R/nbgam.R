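#' Model specification for the PM x wildfire GAMs
#'
#' Describes one fitted model: a single-fraction model (one PM fraction,
#' one lag set, PM x wildfire interaction) or the two-fraction model
#' (lag-0 PM2.5 and PM10-2.5 with their wildfire interactions).  All
#' models share the base structure: intercept, 6 day-of-week indicators,
#' 17 holiday indicators, a penalized cubic regression spline of time,
#' a rolling 7-day temperature average, optional 7-day mean RH, and
#' autoregressive terms `log(1 + visits[t - j])`.
#'
#' @param type `"single"` or `"two_fraction"`.
#' @param fraction PM fraction for single-fraction models.
#' @param lag_set `"0"`, `"0-2"` or `"0-6"` (two-fraction models always
#'   use lag 0).
#' @param temp_metric which daily temperature enters the 7-day rolling
#'   control: `"mean"` (primary), `"min"` or `"max"`.
#' @param include_rh add a rolling 7-day mean relative humidity control.
#' @param pm_scale ug/m3 per PM unit (default 5, so coefficients are per
#'   5 ug/m3).
#' @param spline_basis_size number of knots of the time spline (>= 4).
#' @param ar_lags which visit lags (subset of 1..10) enter as
#'   autoregressive covariates.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(type = c("single", "two_fraction"),
                       fraction = "pm25", lag_set = "0",
                       temp_metric = c("mean", "min", "max"),
                       include_rh = FALSE, pm_scale = 5,
                       spline_basis_size = 10, ar_lags = 1:10) {
  type <- match.arg(type)
  temp_metric <- match.arg(temp_metric)
  if (type == "two_fraction") lag_set <- "0"
  lag_set <- check_lag_set(lag_set)
  fraction <- check_fraction(fraction)
  if (pm_scale <= 0) abort("pm_scale must be > 0",
                           class = "smokegam_argument_error")
  spline_basis_size <- check_scalar_count(spline_basis_size,
                                          "spline_basis_size", min = 4)
  if (length(ar_lags) && !all(ar_lags %in% 1:10))
    abort("ar_lags must be a subset of 1..10",
          class = "smokegam_argument_error")
  structure(list(type = type, fraction = fraction, lag_set = lag_set,
                 temp_metric = temp_metric, include_rh = include_rh,
                 pm_scale = pm_scale,
                 spline_basis_size = spline_basis_size,
                 ar_lags = sort(unique(as.integer(ar_lags)))),
            class = "model_spec")
}

#' Build the merged regression table (study panel)
#'
#' Joins the exposure panel, weather and visit counts on the date index
#' and derives the model covariates: day-of-week and holiday indicators,
#' time index, rolling 7-day means of min/mean/max temperature and RH,
#' and autoregressive covariates `log(1 + visits[t-j])`, j = 1..10.
#'
#' @param exposure an `exposure_panel`.
#' @param weather weather data frame (`date`, `temp_min`, `temp_mean`,
#'   `temp_max`, `rh_mean`).
#' @param visits data frame (`date`, `visits`), non-negative integers.
#' @return an object of class `study_panel`: list with `data` (the merged
#'   table) and `exposure` (kept for monitor-activity columns).
#' @export
build_study_panel <- function(exposure, weather, visits) {
  stopifnot(inherits(exposure, "exposure_panel"))
  d <- exposure$data
  if (!identical(d$date, weather$date) || !identical(d$date, visits$date))
    abort("exposure, weather and visits must share one date index",
          class = "smokegam_argument_error")
  if (any(is.na(visits$visits)) || any(visits$visits < 0) ||
      !all(is_wholenumber(visits$visits)))
    abort("visits must be non-negative integers",
          class = "smokegam_argument_error")
  out <- d
  out$visits <- as.integer(visits$visits)
  out$time <- as.numeric(d$date - d$date[1]) + 1
  out <- cbind(out, dow_indicators(d$date))
  hol <- holiday_indicators(d$date)
  colnames(hol) <- paste0("hol_", colnames(hol))
  out <- cbind(out, hol)
  out$temp_min <- weather$temp_min
  out$temp_mean <- weather$temp_mean
  out$temp_max <- weather$temp_max
  out$rh_mean <- weather$rh_mean
  out$temp7_min <- rolling_mean(weather$temp_min, 7L)
  out$temp7_mean <- rolling_mean(weather$temp_mean, 7L)
  out$temp7_max <- rolling_mean(weather$temp_max, 7L)
  out$rh7 <- rolling_mean(weather$rh_mean, 7L)
  for (j in 1:10) out[[paste0("ar", j)]] <- log1p(lag_vec(out$visits, j))
  structure(list(data = out, exposure = exposure), class = "study_panel")
}

#' Assemble the design bundle for one model
#'
#' Applies the row exclusions (AR and weather warm-up, undefined lag
#' averages, mixed-lag tri-state observations, exceedance-masked
#' wildfire observations, days with no active monitor), builds the model
#' matrix with named roles, the centered spline basis and its penalty
#' (zero outside the spline block), drops unidentifiable constant holiday
#' and monitor-activity columns, and verifies full column rank.
#'
#' @param study a `study_panel`.
#' @param spec a `model_spec`.
#' @return an object of class `design_bundle` with elements `y`, `X`,
#'   `S` (penalty, spline-normalized), `roles`, `spline_idx`, `dates`,
#'   `spec`, `dropped` (names of dropped constant columns) and `basis`.
#' @export
assemble_design <- function(study, spec) {
  stopifnot(inherits(study, "study_panel"), inherits(spec, "model_spec"))
  d <- study$data
  sfx <- lag_suffix(spec$lag_set)
  tempcol <- paste0("temp7_", spec$temp_metric)
  arcols <- paste0("ar", spec$ar_lags)
  keep <- !is.na(d$visits) & !is.na(d[[tempcol]])
  for (ac in arcols) keep <- keep & !is.na(d[[ac]])
  if (spec$include_rh) keep <- keep & !is.na(d$rh7)
  wfcol <- paste0("wf_", sfx)
  exclcol <- paste0("excl_", sfx)
  keep <- keep & !is.na(d[[wfcol]]) & d[[wfcol]] != WF_EXCLUDED &
    !d[[exclcol]]
  pmcols <- if (spec$type == "single") paste0(spec$fraction, "_", sfx)
            else c("pm25_l0", "pm_coarse_l0")
  for (pc in pmcols) keep <- keep & !is.na(d[[pc]])
  idx <- which(keep)
  if (length(idx) < spec$spline_basis_size + 30L)
    abort("too few usable observations (", length(idx),
          ") after exclusions for model fitting",
          class = "smokegam_argument_error")
  dd <- d[idx, ]
  ## spline of time, sum-to-zero centered, penalty normalized so that a
  ## smoothing parameter of order 1 balances fit and penalty
  basis <- cubic_regression_spline_basis(dd$time, spec$spline_basis_size)
  Cm <- matrix(colMeans(basis$X))
  Z <- qr.Q(qr(Cm), complete = TRUE)[, -1, drop = FALSE]
  Xs <- basis$X %*% Z
  Ss <- t(Z) %*% basis$S %*% Z
  Ss <- (Ss + t(Ss)) / 2
  s_scale <- sum(diag(crossprod(Xs))) / sum(diag(Ss))
  Ss <- Ss * s_scale
  colnames(Xs) <- paste0("s(time).", seq_len(ncol(Xs)))

  blocks <- list(
    list(X = matrix(1, nrow(dd), 1, dimnames = list(NULL, "(Intercept)")),
         role = "intercept"),
    list(X = dow_indicators(dd$date), role = "dow"),
    list(X = {
      h <- holiday_indicators(dd$date)
      colnames(h) <- paste0("hol_", colnames(h)); h
    }, role = "holiday"),
    list(X = Xs, role = "spline"),
    list(X = matrix(dd[[tempcol]], ncol = 1,
                    dimnames = list(NULL, tempcol)), role = "temp"))
  if (spec$include_rh)
    blocks <- c(blocks, list(list(X = matrix(dd$rh7, ncol = 1,
                                             dimnames = list(NULL, "rh7")),
                                  role = "rh")))
  arX <- as.matrix(dd[, arcols, drop = FALSE])
  blocks <- c(blocks, list(list(X = arX, role = "ar")))
  wf <- as.numeric(dd[[wfcol]])
  if (spec$type == "single") {
    pm <- dd[[pmcols]] / spec$pm_scale
    expX <- cbind(pm = pm, pm_wf = pm * wf, wf = wf)
    blocks <- c(blocks, list(list(X = expX,
                                  role = c("pm", "pm_wf", "wf"))))
    mon <- study$exposure$activity[[spec$fraction]][[spec$lag_set]][idx, ,
                                                                 drop = FALSE]
    colnames(mon) <- paste0("mon_", spec$fraction, "_", colnames(mon))
    blocks <- c(blocks, list(list(X = mon,
                                  role = rep("monitor", ncol(mon)))))
  } else {
    pm25 <- dd$pm25_l0 / spec$pm_scale
    pmc <- dd$pm_coarse_l0 / spec$pm_scale
    expX <- cbind(pm25 = pm25, pm25_wf = pm25 * wf, pm_coarse = pmc,
                  pm_coarse_wf = pmc * wf, wf = wf)
    blocks <- c(blocks, list(list(
      X = expX,
      role = c("pm25", "pm25_wf", "pm_coarse", "pm_coarse_wf", "wf"))))
    for (f in c("pm25", "pm_coarse")) {
      mon <- study$exposure$activity[[f]][["0"]][idx, , drop = FALSE]
      colnames(mon) <- paste0("mon_", f, "_", colnames(mon))
      blocks <- c(blocks, list(list(X = mon,
                                    role = rep(paste0("monitor_", f),
                                               ncol(mon)))))
    }
  }
  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  roles <- unlist(lapply(blocks, function(b)
    rep(b$role, length.out = ncol(b$X))))
  names(roles) <- colnames(X)
  ## constant holiday/monitor columns are unidentifiable, drop with a note
  droppable <- grepl("^(holiday|monitor)", roles)
  constant <- apply(X, 2, function(col) all(col == col[1]))
  dropped <- colnames(X)[constant & droppable]
  keep_col <- !(constant & droppable)
  X <- X[, keep_col, drop = FALSE]
  roles <- roles[keep_col]
  spline_idx <- which(roles == "spline")
  S <- matrix(0, ncol(X), ncol(X),
              dimnames = list(colnames(X), colnames(X)))
  S[spline_idx, spline_idx] <- Ss
  qx <- qr(X)
  if (qx$rank < ncol(X))
    abort("design is rank deficient; offending column(s): ",
          paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                collapse = ", "),
          class = "smokegam_rank_error")
  structure(list(y = dd$visits, X = X, S = S, roles = roles,
                 spline_idx = spline_idx, dates = dd$date, spec = spec,
                 dropped = dropped, basis = basis),
            class = "design_bundle")
}

as_design_bundle <- function(design) {
  if (inherits(design, "design_bundle")) return(design)
  if (is.list(design) && !is.null(design$y) && !is.null(design$X)) {
    X <- as.matrix(design$X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    S <- design$S %||% matrix(0, ncol(X), ncol(X))
    roles <- design$roles %||%
      stats::setNames(rep("covariate", ncol(X)), colnames(X))
    structure(list(y = design$y, X = X, S = as.matrix(S), roles = roles,
                   spline_idx = design$spline_idx %||% integer(0),
                   dates = design$dates %||% seq_along(design$y),
                   spec = design$spec %||% NULL, dropped = character(0)),
              class = "design_bundle")
  } else abort("design must be a design_bundle or a list with y and X",
               class = "smokegam_argument_error")
}

## negative binomial (NB2) deviance, size parameterization; log1p form
## stays accurate in the large-theta (Poisson) limit
nb_deviance <- function(y, mu, theta) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(t1 - (y + theta) * log1p((y - mu) / (mu + theta)))
}

nb_loglik <- function(y, mu, theta) {
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

## ML update of the NB size parameter given fitted means
theta_ml <- function(y, mu, lower = log(0.05), upper = log(1e7)) {
  f <- function(lt) -nb_loglik(y, mu, exp(lt))
  exp(optimize(f, c(lower, upper), tol = 1e-6)$minimum)
}

#' Penalized IRLS fit of the NB GLM/GAM at fixed smoothing and dispersion
#'
#' Maximizes the negative-binomial log-likelihood minus the quadratic
#' spline penalty `lambda/2 * b' S b` (log link) by penalized iteratively
#' reweighted least squares with step halving.  The coefficient
#' covariance is the inverse penalized Fisher information (the
#' Bayesian-style covariance underlying mgcv-type Wald intervals).
#'
#' @param design a `design_bundle`, or a list with `y`, `X` and
#'   optionally `S`.
#' @param lambda smoothing parameter (>= 0).
#' @param theta NB dispersion (size) parameter; large values approach the
#'   Poisson limit.
#' @param start optional starting coefficients.
#' @param max_iter iteration cap.
#' @param tol relative penalized-deviance convergence tolerance.
#' @return list with `coefficients`, `cov`, `edf` (per-coefficient
#'   effective degrees of freedom), `deviance`, `penalty`, `loglik`,
#'   `fitted`, `eta`, `w`, `z`, `logdet_penalized_info`, `iterations`,
#'   `converged`.
#' @export
fit_penalized_nb_glm <- function(design, lambda, theta, start = NULL,
                                 max_iter = 200L, tol = 1e-11) {
  design <- as_design_bundle(design)
  y <- design$y; X <- design$X; S <- design$S
  if (lambda < 0 || !is.finite(theta) || theta <= 0)
    abort("lambda must be >= 0 and theta > 0",
          class = "smokegam_argument_error")
  n <- nrow(X); p <- ncol(X)
  Sl <- lambda * S
  pen_dev <- function(b, mu) nb_deviance(y, mu, theta) +
    drop(t(b) %*% Sl %*% b)
  beta <- start
  if (is.null(beta)) {
    eta <- log(pmax(y, 0.25) + 0.25)
  } else eta <- drop(X %*% beta)
  mu <- exp(pmin(eta, 30))
  pd_old <- if (is.null(beta)) Inf else pen_dev(beta, mu)
  converged <- FALSE
  Rc <- NULL
  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + mu / theta)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / mu
    A <- crossprod(X * sqrt(w)) + Sl
    Rc <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(Rc)) {
      A <- A + diag(1e-8 * mean(diag(A)), p)
      Rc <- chol(A)
    }
    b <- crossprod(X, w * z)
    beta_new <- backsolve(Rc, backsolve(Rc, b, transpose = TRUE))
    eta_new <- drop(X %*% beta_new)
    mu_new <- exp(pmin(eta_new, 30))
    pd_new <- pen_dev(beta_new, mu_new)
    halvings <- 0L
    while ((!is.finite(pd_new) || pd_new > pd_old + 1e-12) &&
           !is.null(beta) && halvings < 30L) {
      beta_new <- (beta_new + beta) / 2
      eta_new <- drop(X %*% beta_new)
      mu_new <- exp(pmin(eta_new, 30))
      pd_new <- pen_dev(beta_new, mu_new)
      halvings <- halvings + 1L
    }
    ## converge on relative penalized deviance or on coefficient change
    ## (the deviance criterion stalls at machine precision)
    done <- !is.null(beta) &&
      (abs(pd_old - pd_new) / (abs(pd_new) + 0.1) < max(tol, 1e-14) ||
         max(abs(beta_new - beta)) < 1e-11 * (1 + max(abs(beta_new))))
    beta <- drop(beta_new); eta <- eta_new; mu <- mu_new; pd_old <- pd_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 1L)
    abort("penalized IRLS did not converge in ", max_iter,
          " iterations (last penalized deviance ",
          format(pd_old), ")", class = "smokegam_convergence_error")
  ## refresh A at the final iterate
  w <- pmax(mu / (1 + mu / theta), 1e-10)
  z <- eta + (y - mu) / mu
  XtWX <- crossprod(X * sqrt(w))
  A <- XtWX + Sl
  Rc <- chol(A)
  Vb <- chol2inv(Rc)
  edf <- rowSums(Vb * XtWX)
  names(beta) <- colnames(X)
  dimnames(Vb) <- list(colnames(X), colnames(X))
  list(coefficients = beta, cov = Vb, edf = edf,
       deviance = nb_deviance(y, mu, theta),
       penalty = drop(t(beta) %*% S %*% beta),
       loglik = nb_loglik(y, mu, theta), fitted = mu, eta = eta,
       w = w, z = z, logdet_penalized_info = 2 * sum(log(diag(Rc))),
       iterations = iter, converged = converged)
}

## Laplace/working-model REML score (smaller is better), phi = 1
reml_score <- function(fit, lambda, s_rank, s_logdet) {
  prss <- sum(fit$w * (fit$z - fit$eta)^2) + lambda * fit$penalty
  prss + fit$logdet_penalized_info - (s_rank * log(lambda) + s_logdet)
}

gcv_score <- function(fit) {
  n <- length(fit$fitted)
  n * fit$deviance / (n - sum(fit$edf))^2
}

#' Fit the NB GAM with automatic smoothness and dispersion selection
#'
#' Outer loop around [fit_penalized_nb_glm()]: the smoothing parameter is
#' chosen by minimizing a working-model restricted-likelihood (REML-type)
#' score over a log-scale grid refined by golden-section search (GCV
#' fallback when the REML score is non-finite), alternating with 1-D
#' maximum-likelihood updates of the NB dispersion, until the relative
#' deviance change falls below `dev_tol`.
#'
#' @param design a `design_bundle`.
#' @param lambda fixed smoothing parameter, or `NULL` (default) to select
#'   automatically.
#' @param theta fixed NB dispersion, or `NULL` to estimate.
#' @param criterion `"reml"` (default) or `"gcv"`.
#' @param control list: `grid` (log-lambda grid), `golden_iters`,
#'   `max_rounds`, `dev_tol`, `irls_tol`, `max_iter`.
#' @return an object of class `gam_fit`: coefficients, covariance,
#'   smoothing parameter, `spline_edf` (spline effective degrees of
#'   freedom, counting the line as 2), dispersion, deviance, residuals,
#'   convergence metadata, roles and the design.
#' @export
fit_nb_gam <- function(design, lambda = NULL, theta = NULL,
                       criterion = c("reml", "gcv"), control = list()) {
  design <- as_design_bundle(design)
  criterion <- match.arg(criterion)
  ctl <- modifyList(list(grid = seq(-9, 16, length.out = 13),
                         golden_iters = 12L, max_rounds = 6L,
                         dev_tol = 1e-8, irls_tol = 1e-11,
                         max_iter = 200L), control)
  y <- design$y
  spl <- design$spline_idx
  has_spline <- length(spl) > 0
  s_rank <- 0L; s_logdet <- 0
  if (has_spline) {
    ev <- eigen(design$S[spl, spl, drop = FALSE], symmetric = TRUE,
                only.values = TRUE)$values
    pos <- ev > max(ev) * 1e-9
    s_rank <- sum(pos)
    s_logdet <- sum(log(ev[pos]))
  }
  warm <- new.env(parent = emptyenv()); warm$beta <- NULL
  run_pirls <- function(lam, th) {
    ft <- fit_penalized_nb_glm(design, lam, th, start = warm$beta,
                               max_iter = ctl$max_iter, tol = ctl$irls_tol)
    warm$beta <- ft$coefficients
    ft
  }
  score_at <- function(loglam, th) {
    ft <- run_pirls(exp(loglam), th)
    sc <- if (criterion == "reml")
      reml_score(ft, exp(loglam), s_rank, s_logdet) else gcv_score(ft)
    if (!is.finite(sc)) sc <- gcv_score(ft)
    if (!is.finite(sc))
      abort("smoothness criterion non-finite at log(lambda) = ", loglam,
            class = "smokegam_criterion_error")
    sc
  }
  select_lambda <- function(th) {
    grid <- ctl$grid
    sc <- vapply(grid, score_at, numeric(1), th = th)
    i <- which.min(sc)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; bb <- hi
    x1 <- bb - gr * (bb - a); x2 <- a + gr * (bb - a)
    f1 <- score_at(x1, th); f2 <- score_at(x2, th)
    for (k in seq_len(ctl$golden_iters)) {
      if (f1 < f2) {
        bb <- x2; x2 <- x1; f2 <- f1
        x1 <- bb - gr * (bb - a); f1 <- score_at(x1, th)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (bb - a); f2 <- score_at(x2, th)
      }
    }
    exp((a + bb) / 2)
  }
  theta_fixed <- !is.null(theta)
  lambda_fixed <- !is.null(lambda) || !has_spline
  if (!has_spline && is.null(lambda)) lambda <- 0
  if (is.null(theta)) {
    pilot <- run_pirls(if (lambda_fixed) lambda else 1, 10)
    theta <- theta_ml(y, pilot$fitted)
  }
  dev_old <- Inf; rounds <- 0L; fit <- NULL
  repeat {
    rounds <- rounds + 1L
    if (!lambda_fixed) lambda <- select_lambda(theta)
    fit <- run_pirls(lambda, theta)
    if (!theta_fixed) theta <- theta_ml(y, fit$fitted)
    dev <- nb_deviance(y, fit$fitted, theta)
    if (abs(dev_old - dev) / (abs(dev) + 0.1) < ctl$dev_tol ||
        rounds >= ctl$max_rounds) break
    dev_old <- dev
  }
  fit <- run_pirls(lambda, theta)
  mu <- fit$fitted
  dres <- sign(y - mu) *
    sqrt(pmax(0, 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                        (y + theta) * log1p((y - mu) / (mu + theta)))))
  crit_val <- if (criterion == "reml" && has_spline && lambda > 0)
    reml_score(fit, lambda, s_rank, s_logdet) else gcv_score(fit)
  structure(list(coefficients = fit$coefficients, cov = fit$cov,
                 smoothing_parameter = lambda,
                 spline_edf = if (has_spline) 1 + sum(fit$edf[spl])
                              else NA_real_,
                 edf = fit$edf, edf_total = sum(fit$edf),
                 nb_dispersion = theta, deviance = fit$deviance,
                 loglik = fit$loglik, criterion = criterion,
                 criterion_value = crit_val,
                 iterations = rounds, converged = fit$converged,
                 fitted = mu, residuals_working = fit$z - fit$eta,
                 residuals_deviance = dres, dates = design$dates,
                 roles = design$roles, spec = design$spec,
                 dropped = design$dropped, design = design),
            class = "gam_fit")
}

#' @rdname fit_nb_gam
#' @export
select_smoothness <- function(design, criterion = c("reml", "gcv"),
                              control = list()) {
  fit_nb_gam(design, lambda = NULL, theta = NULL, criterion = criterion,
             control = control)
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("Negative-binomial GAM fit\n")
  if (!is.null(x$spec))
    cat("  model: ", x$spec$type, " fraction=", x$spec$fraction,
        " lags=", x$spec$lag_set, "\n", sep = "")
  cat(sprintf("  n = %d, deviance = %.2f, dispersion = %.3f\n",
              length(x$fitted), x$deviance, x$nb_dispersion))
  cat(sprintf("  smoothing parameter = %.4g, spline edf = %.2f (%s)\n",
              x$smoothing_parameter, x$spline_edf, x$criterion))
  invisible(x)
}

#' Residual autocorrelation diagnostics
#'
#' Sample ACF and partial ACF of the deviance residuals, with the
#' +-1.96/sqrt(n) white-noise reference band.
#'
#' @param fit a `gam_fit`.
#' @param max_lag largest lag (must be < series length).
#' @return list with `lag`, `acf` (lags 0..max_lag), `pacf` (lags
#'   1..max_lag) and `band`.
#' @export
residual_acf <- function(fit, max_lag = 30L) {
  stopifnot(inherits(fit, "gam_fit"))
  r <- fit$residuals_deviance
  max_lag <- check_scalar_count(max_lag, "max_lag")
  if (max_lag >= length(r))
    abort("max_lag must be smaller than the residual series length",
          class = "smokegam_argument_error")
  a <- acf(r, lag.max = max_lag, plot = FALSE, demean = TRUE)
  p <- pacf(r, lag.max = max_lag, plot = FALSE)
  list(lag = 0:max_lag, acf = drop(a$acf), pacf = drop(p$acf),
       band = 1.96 / sqrt(length(r)))
}
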