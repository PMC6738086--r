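#' Positive-part cube
#'
#' The truncated cubic `(x - knot)_+^3 = max(0, x - knot)^3`, the building
#' block of the restricted cubic spline basis.
#'
#' @param x Numeric vector.
#' @param knot Scalar knot position.
#' @return `max(0, x - knot)^3`, vectorised over `x`.
#' @export
truncated_cube <- function(x, knot) {
  pmax(0, x - knot)^3
}

#' Restricted cubic spline on log time
#'
#' Constructs the spline object that carries the log baseline cumulative
#' hazard, s(log t): boundary knots, internal knots and coefficients
#' gamma_0 ... gamma_{m+1} (m internal knots), all on the natural-log
#' months scale.
#'
#' @param boundary_knots Length-2 numeric, `(k_min, k_max)` on log-months.
#' @param internal_knots Ordered numeric vector of internal knots (may be
#'   empty, giving a Weibull-equivalent log-linear baseline).
#' @param gamma Coefficient vector of length `2 + length(internal_knots)`.
#' @return An object of class `"rcs_log_time"`.
#' @export
rcs_log_time <- function(boundary_knots, internal_knots = numeric(0), gamma) {
  stopifnot(length(boundary_knots) == 2L)
  boundary_knots <- as.numeric(boundary_knots)
  internal_knots <- as.numeric(internal_knots)
  gamma <- as.numeric(gamma)
  if (boundary_knots[1] >= boundary_knots[2])
    stop("boundary knots must satisfy k_min < k_max")
  if (length(internal_knots) &&
      (is.unsorted(internal_knots, strictly = TRUE) ||
       min(internal_knots) <= boundary_knots[1] ||
       max(internal_knots) >= boundary_knots[2]))
    stop("internal knots must be strictly ordered and lie strictly inside the boundary knots")
  if (length(gamma) != 2L + length(internal_knots))
    stop("gamma must have length 2 + number of internal knots, got ", length(gamma))
  structure(
    list(boundary_knots = boundary_knots,
         internal_knots = internal_knots,
         gamma = gamma),
    class = "rcs_log_time"
  )
}

#' @export
print.rcs_log_time <- function(x, ...) {
  cat("Restricted cubic spline on log time (months)\n")
  cat("  boundary knots:", format(x$boundary_knots, digits = 4), "\n")
  if (length(x$internal_knots))
    cat("  internal knots:", format(x$internal_knots, digits = 4), "\n")
  else
    cat("  internal knots: none (log-linear baseline)\n")
  cat("  gamma:", format(x$gamma, digits = 4), "\n")
  invisible(x)
}

#' Knot weights of the restricted basis
#'
#' `lambda_j = (k_max - k_j) / (k_max - k_min)` for each internal knot; the
#' weights that make the basis linear beyond the boundary knots.
#'
#' @param spline An [rcs_log_time()] object.
#' @return Numeric vector of weights in (0, 1), one per internal knot.
#' @export
knot_lambdas <- function(spline) {
  k <- spline$boundary_knots
  (k[2] - spline$internal_knots) / (k[2] - k[1])
}

#' Spline basis matrix on the log-time scale
#'
#' Columns are the restricted-cubic basis functions evaluated at `x`
#' (already on the log scale): `1, x, z_1(x), ..., z_m(x)` with
#' `z_j(x) = (x - k_j)_+^3 - lambda_j (x - k_min)_+^3 -
#' (1 - lambda_j)(x - k_max)_+^3`.
#'
#' @param x Numeric vector on the log-months scale.
#' @param spline An [rcs_log_time()] object (its `gamma` is ignored here).
#' @param derivative If `TRUE`, return d/dx of each basis column instead.
#' @return Matrix with `length(x)` rows and `2 + m` columns.
#' @export
spline_basis <- function(x, spline, derivative = FALSE) {
  k <- spline$boundary_knots
  ik <- spline$internal_knots
  lam <- knot_lambdas(spline)
  m <- length(ik)
  out <- matrix(0, length(x), 2L + m)
  if (derivative) {
    out[, 1L] <- 0
    out[, 2L] <- 1
    for (j in seq_len(m)) {
      out[, 2L + j] <- 3 * (pmax(0, x - ik[j])^2 -
                            lam[j] * pmax(0, x - k[1])^2 -
                            (1 - lam[j]) * pmax(0, x - k[2])^2)
    }
  } else {
    out[, 1L] <- 1
    out[, 2L] <- x
    for (j in seq_len(m)) {
      out[, 2L + j] <- truncated_cube(x, ik[j]) -
        lam[j] * truncated_cube(x, k[1]) -
        (1 - lam[j]) * truncated_cube(x, k[2])
    }
  }
  out
}

#' Log baseline cumulative hazard
#'
#' Evaluates s(log t) = gamma_0 + gamma_1 log t + sum_j gamma_{j+1} z_j(log t)
#' with natural logs and t in months.  Beyond the boundary knots the
#' restricted basis is linear in log t, so extrapolation is log-linear.
#'
#' @param t Time in months, strictly positive (vectorised).
#' @param spline An [rcs_log_time()] object.
#' @return s(log t), numeric vector.
#' @export
spline_log_cum_hazard <- function(t, spline) {
  if (any(t <= 0)) stop("time must be strictly positive (months)")
  drop(spline_basis(log(t), spline) %*% spline$gamma)
}

#' Derivative of s with respect to log t
#'
#' Needed by the hazard function and the fitting likelihood; must be
#' positive wherever an event occurs.
#'
#' @inheritParams spline_log_cum_hazard
#' @return ds/d(log t), numeric vector.
#' @keywords internal
spline_log_cum_hazard_deriv <- function(t, spline) {
  if (any(t <= 0)) stop("time must be strictly positive (months)")
  drop(spline_basis(log(t), spline, derivative = TRUE) %*% spline$gamma)
}

#' Baseline survival function
#'
#' S0(t) = exp(-exp(s(log t))): the survival of a subject whose linear
#' predictor is zero.
#'
#' @inheritParams spline_log_cum_hazard
#' @return Survival probabilities in (0, 1).
#' @export
baseline_survival <- function(t, spline) {
  exp(-exp(spline_log_cum_hazard(t, spline)))
}

#' Invert the spline: time at which s(log t) reaches a target
#'
#' Monotone root-finding on the log-time scale; assumes s is increasing,
#' which holds for any fitted model with positive hazard over its range.
#' Used for simulating event times and locating median survival.
#'
#' @param target Value(s) of s(log t) to invert.
#' @param spline An [rcs_log_time()] object.
#' @return Time(s) in months.
#' @keywords internal
spline_inverse <- function(target, spline) {
  vapply(target, function(g) {
    f <- function(x) drop(spline_basis(x, spline) %*% spline$gamma) - g
    lo <- spline$boundary_knots[1] - 20
    hi <- spline$boundary_knots[2] + 20
    # widen until bracketed; s is linear beyond the knots so this terminates
    while (f(lo) > 0) lo <- lo - 20
    while (f(hi) < 0) hi <- hi + 20
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }, numeric(1))
}
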