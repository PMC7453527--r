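`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class = "smokegam_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    abort(name, " must be a single integer >= ", min,
          class = "smokegam_argument_error")
  as.integer(x)
}

check_lag_set <- function(lag_set) {
  lag_set <- as.character(lag_set)
  if (length(lag_set) != 1L || !lag_set %in% names(LAG_SETS))
    abort("unknown lag set '", lag_set, "'; must be one of ",
          paste(names(LAG_SETS), collapse = ", "),
          class = "smokegam_argument_error")
  lag_set
}

check_fraction <- function(fraction) {
  fraction <- as.character(fraction)
  if (length(fraction) != 1L || !fraction %in% names(PM_FRACTIONS))
    abort("unknown PM fraction '", fraction, "'; must be one of ",
          paste(names(PM_FRACTIONS), collapse = ", "),
          class = "smokegam_argument_error")
  fraction
}

## suffix used for lag-set-specific columns: "0" -> l0, "0-2" -> l02
lag_suffix <- function(lag_set) paste0("l", gsub("-", "", lag_set))

## x lagged by k days (NA-padded head)
lag_vec <- function(x, k) {
  if (k == 0L) return(x)
  c(rep(NA_real_, k), x[seq_len(length(x) - k)])
}

## rolling mean over a trailing window of `width` days, NA whenever any
## included day is NA (missingness propagates; leading window undefined)
rolling_mean <- function(x, width) {
  n <- length(x)
  if (width == 1L) return(as.numeric(x))
  if (n < width) return(rep(NA_real_, n))
  out <- rep(NA_real_, n)
  out[width:n] <- rowMeans(embed(as.numeric(x), width))
  out
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < tol
}
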