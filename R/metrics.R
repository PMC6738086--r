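#' Harrell's concordance index
#'
#' Proportion of comparable patient pairs whose risk-score ranking agrees
#' with their survival ranking.  A pair (i, j) is comparable when
#' `t_i < t_j` and subject i died; concordant when the shorter-lived member
#' carries the higher risk score; score ties count one half.  Tied times are
#' comparable only when exactly one member is an event (that member must
#' rank riskier).
#'
#' @param times Observed times.
#' @param events Event indicators (1 = death).
#' @param risk_scores Higher = predicted to die sooner (e.g. the linear
#'   predictor).
#' @return c-index in `[0, 1]`.
#' @export
harrells_c <- function(times, events, risk_scores) {
  n <- length(times)
  stopifnot(length(events) == n, length(risk_scores) == n)
  concordant <- 0; ties <- 0; comparable <- 0
  for (i in which(events == 1)) {
    comp <- times > times[i] | (times == times[i] & events == 0)
    comparable <- comparable + sum(comp)
    concordant <- concordant + sum(comp & risk_scores[i] > risk_scores)
    ties <- ties + sum(comp & risk_scores[i] == risk_scores)
  }
  if (comparable == 0) stop("no comparable pairs")
  (concordant + 0.5 * ties) / comparable
}

# kappa scaling constant of the D statistic
kappa_d <- sqrt(8 / pi)

#' Royston-Sauerbrei D statistic
#'
#' Discrimination on the log relative-hazard scale: the prognostic index is
#' rank-transformed to standard-normal order statistics (Blom scores
#' `qnorm((r - 3/8) / (n + 1/4))`), scaled by `kappa = sqrt(8/pi)`, and the
#' coefficient of this constructed covariate in an auxiliary
#' proportional-hazards fit on the same survival outcome is D.  D is the
#' log hazard ratio between the prognostically better and worse halves of
#' the cohort under normality of the index.
#'
#' @param times Observed times (months).
#' @param events Event indicators.
#' @param prognostic_index Linear predictor values.
#' @param df Spline df of the auxiliary flexible parametric fit.
#' @return D (real; 0 for a constant index, with a warning).
#' @export
royston_sauerbrei_d <- function(times, events, prognostic_index, df = 2) {
  n <- length(times)
  stopifnot(length(events) == n, length(prognostic_index) == n)
  if (n < 10 || sum(events) < 2)
    stop("need at least 10 subjects and 2 events")
  if (stats::sd(prognostic_index) == 0) {
    warning("constant prognostic index; D = 0")
    return(0)
  }
  r <- rank(prognostic_index, ties.method = "average")
  a <- stats::qnorm((r - 3 / 8) / (n + 1 / 4)) / kappa_d
  dat <- data.frame(time = times, event = events, a = a)
  fit <- flexpar(survival::Surv(time, event) ~ a, dat, df = df)
  unname(fit$beta["a"])
}

#' Explained variation R2_D from D
#'
#' `R2_D = (D^2 / kappa^2) / (sigma^2 + D^2 / kappa^2)` with
#' `kappa^2 = 8/pi` and `sigma^2 = pi^2/6`, the variance of the standard
#' extreme-value distribution underlying the proportional-hazards model.
#'
#' @param D The D statistic.
#' @return R2_D in `[0, 1)`.
#' @export
r2_from_d <- function(D) {
  v <- D^2 / (8 / pi)
  v / (pi^2 / 6 + v)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows of `data` with replacement `reps` times, applies
#' `statistic`, and returns the percentile interval.  A resample on which
#' the statistic fails (e.g. a degenerate fit) is redrawn, up to a capped
#' number of retries.
#'
#' @param data Data frame of rows to resample.
#' @param statistic Function of a data frame returning a scalar.
#' @param reps Number of bootstrap resamples (>= 2); 200 mirrors the
#'   model's published validation.
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param conf_level Confidence level.
#' @return List with `lower`, `upper`, the vector of `replicates`, and
#'   `retries` (count of redrawn resamples).
#' @export
bootstrap_ci <- function(data, statistic, reps = 200, seed = 1,
                         conf_level = 0.95) {
  stopifnot(reps >= 2)
  n <- nrow(data)
  set.seed(seed)
  vals <- numeric(reps)
  retries <- 0L
  max_retries <- 10L * reps
  for (b in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(v) && is.finite(v)) { vals[b] <- v; break }
      retries <- retries + 1L
      if (retries > max_retries)
        stop("bootstrap statistic failed on too many resamples")
    }
  }
  alpha <- 1 - conf_level
  q <- unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2)))
  list(lower = q[1], upper = q[2], replicates = vals, retries = retries)
}

#' Discrimination summary with bootstrap intervals
#'
#' Computes Harrell's c-index, the D statistic and R2_D for a prognostic
#' index on right-censored outcomes, with percentile bootstrap confidence
#' intervals.
#'
#' @inheritParams royston_sauerbrei_d
#' @param reps Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `"discrimination_result"`: `c_index`, `c_index_ci`,
#'   `D`, `D_ci`, `r2_d`, `r2_d_ci`, `n_comparable_pairs`, `reps`, `seed`.
#' @export
discrimination <- function(times, events, prognostic_index,
                           reps = 200, seed = 1) {
  cidx <- harrells_c(times, events, prognostic_index)
  D <- royston_sauerbrei_d(times, events, prognostic_index)
  dat <- data.frame(time = times, event = events, pi = prognostic_index)
  cb <- bootstrap_ci(dat, function(d) harrells_c(d$time, d$event, d$pi),
                     reps = reps, seed = seed)
  db <- bootstrap_ci(dat,
                     function(d) royston_sauerbrei_d(d$time, d$event, d$pi),
                     reps = reps, seed = seed + 1L)
  n <- length(times)
  ncomp <- 0
  for (i in seq_len(n)) if (events[i] == 1)
    ncomp <- ncomp + sum(times > times[i]) +
      sum(times == times[i] & events == 0)
  structure(
    list(c_index = cidx, c_index_ci = c(cb$lower, cb$upper),
         D = D, D_ci = c(db$lower, db$upper),
         r2_d = r2_from_d(D),
         r2_d_ci = sort(r2_from_d(c(db$lower, db$upper))),
         n_comparable_pairs = ncomp, reps = reps, seed = seed),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("Discrimination (", x$reps, "-sample bootstrap CIs)\n", sep = "")
  cat(sprintf("  Harrell's c-index: %.3f (%.3f, %.3f)\n",
              x$c_index, x$c_index_ci[1], x$c_index_ci[2]))
  cat(sprintf("  D statistic:       %.3f (%.3f, %.3f)\n",
              x$D, x$D_ci[1], x$D_ci[2]))
  cat(sprintf("  R2_D:              %.3f (%.3f, %.3f)\n",
              x$r2_d, x$r2_d_ci[1], x$r2_d_ci[2]))
  invisible(x)
}
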