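#' Cubic regression spline basis with curvature penalty
#'
#' Knot-based cubic regression spline in the value parameterization: the
#' coefficients are the spline's values at the knots, second derivatives
#' at interior knots are determined by natural-spline continuity
#' conditions, and the penalty matrix is the integrated squared second
#' derivative.  Any linear function of `x` lies in the penalty null space
#' (the penalty has exactly two zero eigenvalues).
#'
#' @param x evaluation points (must lie within the knot range).
#' @param n_basis number of knots/basis functions (>= 4).
#' @param knots optional strictly increasing knot vector; default: evenly
#'   spaced quantiles of the unique values of `x`.
#' @return list of class `cr_basis` with `X` (length(x) x n_basis design),
#'   `S` (n_basis x n_basis penalty, symmetric PSD, rank n_basis - 2) and
#'   `knots`.
#' @export
cubic_regression_spline_basis <- function(x, n_basis = 10, knots = NULL) {
  n_basis <- check_scalar_count(n_basis, "n_basis", min = 4)
  if (is.null(knots)) {
    ux <- sort(unique(x))
    if (length(ux) < n_basis)
      abort("need at least n_basis = ", n_basis, " distinct points, got ",
            length(ux), class = "smokegam_argument_error")
    knots <- unname(quantile(ux, probs = seq(0, 1, length.out = n_basis),
                             type = 7))
    if (any(diff(knots) <= 0))
      knots <- seq(min(ux), max(ux), length.out = n_basis)
  }
  K <- length(knots)
  if (any(diff(knots) <= 0))
    abort("knots must be strictly increasing",
          class = "smokegam_argument_error")
  if (any(x < knots[1] - 1e-8 | x > knots[K] + 1e-8))
    abort("x outside knot range", class = "smokegam_argument_error")
  h <- diff(knots)
  ## D (K-2 x K) and B (K-2 x K-2): natural-spline continuity system
  D <- matrix(0, K - 2, K)
  B <- matrix(0, K - 2, K - 2)
  for (i in seq_len(K - 2)) {
    D[i, i] <- 1 / h[i]
    D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < K - 2) {
      B[i, i + 1] <- h[i + 1] / 6
      B[i + 1, i] <- h[i + 1] / 6
    }
  }
  Binv <- solve(B)
  Ffull <- rbind(0, Binv %*% D, 0)  # values -> second derivatives at knots
  S <- t(D) %*% Binv %*% D
  S <- (S + t(S)) / 2
  ## evaluate
  xx <- pmin(pmax(x, knots[1]), knots[K])
  j <- findInterval(xx, knots, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), K - 1L)
  hj <- h[j]
  am <- (knots[j + 1] - xx) / hj
  ap <- (xx - knots[j]) / hj
  cm <- ((knots[j + 1] - xx)^3 / hj - hj * (knots[j + 1] - xx)) / 6
  cp <- ((xx - knots[j])^3 / hj - hj * (xx - knots[j])) / 6
  X <- matrix(0, length(x), K)
  for (i in seq_along(x)) {
    X[i, j[i]] <- am[i]
    X[i, j[i] + 1] <- X[i, j[i] + 1] + ap[i]
    X[i, ] <- X[i, ] + cm[i] * Ffull[j[i], ] + cp[i] * Ffull[j[i] + 1, ]
  }
  structure(list(X = X, S = S, knots = knots), class = "cr_basis")
}
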