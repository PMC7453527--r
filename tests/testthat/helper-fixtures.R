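## Tiny hand-built fixtures and independent oracles used across tests.

## build a monitor_panel from a list of per-monitor value matrices
## (columns pm25, pm_coarse, pm10) and an activity matrix per monitor
tiny_panel <- function(dates, values, active = NULL, weights = NULL) {
  n_mon <- length(values)
  weights <- weights %||% rep(1, n_mon)
  rows <- list()
  for (m in seq_len(n_mon)) {
    vm <- values[[m]]
    am <- if (is.null(active)) matrix(1L, nrow(vm), 3) else active[[m]]
    for (f in seq_along(colnames(vm))) {
      frac <- colnames(vm)[f]
      rows[[length(rows) + 1L]] <- data.frame(
        monitor_id = sprintf("M%02d", m), date = dates, fraction = frac,
        value = ifelse(am[, f] == 1L, vm[, f], NA_real_),
        active = as.integer(am[, f]))
    }
  }
  monitor_panel(do.call(rbind, rows),
                data.frame(monitor_id = sprintf("M%02d", seq_len(n_mon)),
                           weight = weights))
}

tiny_calendar <- function(dates, smoke_hours) {
  structure(data.frame(date = dates, smoke_hours = as.integer(smoke_hours),
                       wf_day = smoke_hours >= 1L),
            class = c("wildfire_calendar", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## textbook unpenalized IRLS for the NB GLM (log link), written
## independently of the package internals: the oracle for fixed-theta fits
oracle_irls_nb <- function(y, X, theta, iters = 200, tol = 1e-13) {
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1L))
  for (i in seq_len(iters)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    W <- diag(drop(mu / (1 + mu / theta)), nrow(X))
    z <- eta + (y - mu) / mu
    beta_new <- drop(solve(t(X) %*% W %*% X, t(X) %*% W %*% z))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

## day-by-day brute-force recomputation of every exposure column for one
## fraction/lag set; deliberately loop-based and independent of the
## vectorized implementation
brute_exposure <- function(panel, calendar, lag_set) {
  lags <- list("0" = 0L, "0-2" = 0:2, "0-6" = 0:6)[[lag_set]]
  n <- length(panel$dates)
  wgt <- setNames(panel$monitors$weight, panel$monitors$monitor_id)
  daily <- function(frac, t) {
    d <- panel$data
    sel <- d$fraction == frac & d$date == panel$dates[t] &
      d$active == 1L & !is.na(d$value)
    if (!any(sel)) return(NA_real_)
    w <- wgt[d$monitor_id[sel]]
    sum(w * d$value[sel]) / sum(w)
  }
  out <- data.frame(date = panel$dates)
  for (frac in c("pm25", "pm_coarse", "pm10")) {
    v <- vapply(seq_len(n), daily, numeric(1), frac = frac)
    out[[frac]] <- v
    avg <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      if (t - max(lags) < 1L) next
      window <- v[t - lags]
      avg[t] <- if (anyNA(window)) NA_real_ else mean(window)
    }
    out[[paste0(frac, "_avg")]] <- avg
  }
  wf <- calendar$wf_day
  ind <- rep(NA_integer_, n)
  for (t in seq_len(n)) {
    if (t - max(lags) < 1L) next
    win <- wf[t - lags]
    ind[t] <- if (all(win)) 1L else if (!any(win)) 0L else -1L
  }
  out$wf_ind <- ind
  thr <- max(out$pm25_avg[!is.na(ind) & ind == 0L], na.rm = TRUE)
  out$mask <- !is.na(ind) & ind == 1L & !is.na(out$pm25_avg) &
    out$pm25_avg > thr
  attr(out, "threshold") <- thr
  out
}

## fast-but-thorough fitting control for simulation loops
sim_fit_control <- function() {
  list(grid = seq(-7, 13, length.out = 9), golden_iters = 8L,
       max_rounds = 3L)
}

## one replicate of the parameter-recovery simulation: simulate a study,
## fit the correctly specified lag-0 PM2.5 model, return estimate/se
recovery_replicate <- function(seed, n_days = 2192, truth = true_params()) {
  sim <- simulate_study(n_days, seed = seed, truth = truth)
  study <- build_study_panel(sim$exposure, sim$weather, sim$visits)
  fit <- fit_nb_gam(assemble_design(study, model_spec("single", "pm25",
                                                      "0")),
                    control = sim_fit_control())
  i <- which(fit$roles == "pm_wf")
  c(est = unname(fit$coefficients[i]), se = sqrt(fit$cov[i, i]))
}
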