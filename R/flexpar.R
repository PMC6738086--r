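#' Knot placement for the baseline spline
#'
#' Boundary knots at the minimum and maximum of the log *uncensored*
#' survival times; `df - 1` internal knots at equally spaced centiles of
#' the log uncensored times (df = 2 gives the median, df = 3 the 33rd and
#' 67th centiles).  df = 1 is the Weibull-equivalent log-linear baseline
#' with no internal knots.
#'
#' @param time Observed times in months.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param df Spline degrees of freedom, >= 1.
#' @return List with `boundary_knots` and `internal_knots` on log-months.
#' @export
place_knots <- function(time, event, df) {
  stopifnot(df >= 1)
  lt <- log(time[event == 1])
  if (length(unique(lt)) < df + 1L)
    stop("need at least df + 1 = ", df + 1L,
         " distinct uncensored times to place knots, have ",
         length(unique(lt)))
  boundary <- range(lt)
  internal <- if (df > 1) {
    probs <- seq(0, 1, length.out = df + 1L)[2:df]
    unname(stats::quantile(lt, probs))
  } else numeric(0)
  if (length(internal) && (min(internal) <= boundary[1] ||
                           max(internal) >= boundary[2]))
    stop("internal knots collide with boundary knots; too few distinct event times")
  list(boundary_knots = boundary, internal_knots = internal)
}

# Assemble the time-basis matrices for the log cumulative hazard, including
# any covariate-by-basis time-dependent blocks.  Returns B, Bp (derivative),
# and column names; td columns multiply the non-constant basis functions.
flexpar_time_design <- function(logt, spline, X, td) {
  B <- spline_basis(logt, spline)
  Bp <- spline_basis(logt, spline, derivative = TRUE)
  nb <- ncol(B)
  gnames <- paste0("gamma", seq_len(nb) - 1L)
  if (length(td)) {
    for (cv in td) {
      xv <- X[, cv]
      B <- cbind(B, xv * B[, -1L, drop = FALSE])
      Bp <- cbind(Bp, xv * Bp[, -1L, drop = FALSE])
      gnames <- c(gnames, paste0(cv, ":b", seq_len(nb - 1L)))
    }
  }
  list(B = B, Bp = Bp, names = gnames)
}

# Log-likelihood, analytic gradient and Hessian for the spline model on the
# log cumulative hazard.  theta = (gamma/td coefficients, beta).  Hazard
# positivity at event times is enforced softly: violations return a large
# negative penalised value with a subgradient so the optimiser can retreat.
flexpar_objective <- function(theta, B, Bp, X, logt, event, ntime) {
  th_t <- theta[seq_len(ntime)]
  beta <- theta[-seq_len(ntime)]
  s <- drop(B %*% th_t)
  sp <- drop(Bp %*% th_t)
  lp <- if (length(beta)) drop(X %*% beta) else rep(0, length(s))
  d <- event
  bad <- d == 1 & sp <= 0
  if (any(bad)) {
    pen <- sum(pmax(0, -sp[bad])) + 1e-3 * sum(bad)
    # d loglik / d theta_t = +1e6 * sum over violating rows of Bp_i
    return(list(loglik = -1e10 - 1e6 * pen,
                grad = c(1e6 * colSums(Bp[bad, , drop = FALSE]),
                         numeric(length(beta))),
                hess = NULL, valid = FALSE))
  }
  eta <- s + lp
  E <- exp(eta)
  ev <- d == 1   # event-only terms: sp may be negative at censored rows
  ll <- sum(log(sp[ev]) - logt[ev] + eta[ev]) - sum(E)
  w_t <- d / ifelse(sp > 0, sp, 1)
  g_t <- colSums((w_t * Bp) + (d - E) * B)
  g_b <- if (length(beta)) colSums((d - E) * X) else numeric(0)
  # Hessian blocks
  Wq <- w_t / ifelse(sp > 0, sp, 1)       # d / sp^2
  H_tt <- -crossprod(Bp * Wq, Bp) - crossprod(B * E, B)
  if (length(beta)) {
    H_tb <- -crossprod(B * E, X)
    H_bb <- -crossprod(X * E, X)
    hess <- rbind(cbind(H_tt, H_tb), cbind(t(H_tb), H_bb))
  } else hess <- H_tt
  list(loglik = ll, grad = c(g_t, g_b), hess = hess, valid = TRUE)
}

#' Log-likelihood of the spline survival model
#'
#' Right-censored log-likelihood of the log-cumulative-hazard spline model
#' at given parameters: each subject contributes
#' `d * (log s'(log t) - log t + s(log t) + x'beta) - exp(s(log t) + x'beta)`.
#' Where the spline slope `s'` is non-positive at an event time (negative
#' hazard) the value is `-Inf` rather than an error, so optimisers can
#' retreat.
#'
#' @param gamma Baseline spline coefficients (length 2 + internal knots).
#' @param beta Covariate coefficients (may be empty).
#' @param time,event Outcome vectors (months; 1 = death).
#' @param X Design matrix matching `beta` (or `NULL` for a null model).
#' @param knots List with `boundary_knots`, `internal_knots` (log-months).
#' @return Scalar log-likelihood, possibly `-Inf`.
#' @export
flexpar_loglik <- function(gamma, beta = numeric(0), time, event,
                           X = NULL, knots) {
  if (is.null(X)) X <- matrix(0, length(time), 0)
  X <- as.matrix(X)
  spline <- rcs_log_time(knots$boundary_knots, knots$internal_knots, gamma)
  tdes <- flexpar_time_design(log(time), spline, X, td = NULL)
  o <- flexpar_objective(c(gamma, beta), tdes$B, tdes$Bp, X, log(time),
                         event, ncol(tdes$B))
  if (!o$valid) return(-Inf)
  o$loglik
}

# Kaplan-Meier-seeded start for the baseline coefficients: regress
# log(-log KM) on the spline basis at event times; beta and td start at 0.
flexpar_init <- function(time, event, spline) {
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  sm <- summary(km, times = sort(unique(time[event == 1])), extend = TRUE)
  keep <- sm$surv > 0 & sm$surv < 1
  nb <- 2L + length(spline$internal_knots)
  if (sum(keep) >= nb) {
    y <- log(-log(sm$surv[keep]))
    Bk <- spline_basis(log(sm$time[keep]), spline)
    fit <- stats::lm.fit(Bk, y)
    g <- fit$coefficients
    g[is.na(g)] <- 0
    # make sure the start is increasing in log t at the event times
    if (all(drop(spline_basis(log(time[event == 1]), spline,
                              derivative = TRUE) %*% g) > 0))
      return(g)
  }
  c(-5, 1, rep(0, nb - 2L))
}

#' Fit a flexible parametric survival model
#'
#' Maximum-likelihood fitting of a proportional-hazards survival model whose
#' log baseline cumulative hazard is a restricted cubic spline in log time
#' (the Royston-Parmar model).  Optimisation is quasi-Newton from a
#' Kaplan-Meier-seeded start with analytic gradients, followed by Newton
#' polishing with the analytic Hessian; convergence requires gradient
#' infinity-norm below `gtol`.  Hazard-positivity violations during the
#' search are rejected softly via a penalised likelihood rather than a hard
#' constraint.
#'
#' @param formula A formula with a [survival::Surv] response (time in
#'   months, event 1 = death) and covariate terms; `~ 1` fits the baseline
#'   alone.
#' @param data Data frame containing the variables.
#' @param df Spline degrees of freedom (1 = Weibull-equivalent).
#' @param knots Optional list with `boundary_knots` and `internal_knots`
#'   (log-months); by default placed by [place_knots()].
#' @param td Character vector of design-matrix column names given
#'   time-dependent effects (covariate-by-spline-basis interactions).
#' @param gtol Gradient infinity-norm convergence threshold.
#' @param maxit Iteration cap for each optimisation stage.
#' @return Object of class `"flexpar"`: fitted `spline`, `beta`, `td`
#'   coefficients, `vcov`, `loglik`, `n`, `nevent`, convergence record and
#'   the model frame ingredients needed by the diagnostic tools.
#' @export
flexpar <- function(formula, data, df = 2, knots = NULL, td = NULL,
                    gtol = 1e-6, maxit = 200) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y)) stop("response must be a survival::Surv object")
  time <- y[, 1]; event <- y[, 2]
  if (any(time <= 0)) stop("times must be strictly positive")
  if (sum(event) < 1) stop("need at least one event to fit")
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  asgn <- attr(X, "assign")
  keep <- asgn != 0L
  X <- X[, keep, drop = FALSE]
  asgn <- asgn[keep]
  if (length(td) && !all(td %in% colnames(X)))
    stop("td covariates not in the design matrix: ",
         paste(setdiff(td, colnames(X)), collapse = ", "))

  if (is.null(knots)) knots <- place_knots(time, event, df)
  spline0 <- rcs_log_time(knots$boundary_knots, knots$internal_knots,
                          gamma = rep(0, 2L + length(knots$internal_knots)))
  logt <- log(time)
  tdes <- flexpar_time_design(logt, spline0, X, td)
  ntime <- ncol(tdes$B)
  nb <- 2L + length(knots$internal_knots)

  g0 <- flexpar_init(time, event, spline0)
  theta <- c(g0, rep(0, ntime - nb), rep(0, ncol(X)))

  obj <- function(th) flexpar_objective(th, tdes$B, tdes$Bp, X, logt, event, ntime)
  ll0 <- obj(theta)$loglik

  opt <- stats::optim(theta, fn = function(th) -obj(th)$loglik,
                      gr = function(th) -obj(th)$grad,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  theta <- opt$par
  # Newton polish to drive the gradient to machine-level zero
  iter_newton <- 0L
  repeat {
    o <- obj(theta)
    gnorm <- max(abs(o$grad))
    if (!o$valid || gnorm < gtol || iter_newton >= 50L) break
    step <- tryCatch(solve(o$hess, o$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_theta <- theta - step
    halv <- 0L
    while (obj(new_theta)$loglik < o$loglik - 1e-12 && halv < 30L) {
      step <- step / 2; new_theta <- theta - step; halv <- halv + 1L
    }
    if (obj(new_theta)$loglik < o$loglik - 1e-12) break
    theta <- new_theta
    iter_newton <- iter_newton + 1L
  }
  o <- obj(theta)
  gnorm <- max(abs(o$grad))
  if (!o$valid || !is.finite(o$loglik) || gnorm > 1e-3)
    stop("flexpar did not converge: gradient infinity-norm ", format(gnorm),
         " after ", opt$counts[1], " quasi-Newton and ", iter_newton,
         " Newton iterations")
  if (o$loglik < ll0 - 1e-8)
    stop("optimiser finished below its starting log-likelihood")

  vcov <- tryCatch({
    v <- solve(-o$hess)
    (v + t(v)) / 2
  }, error = function(e) matrix(NA_real_, length(theta), length(theta)))

  th_t <- theta[seq_len(ntime)]
  gamma <- th_t[seq_len(nb)]
  delta <- th_t[-seq_len(nb)]
  beta <- theta[-seq_len(ntime)]
  names(beta) <- colnames(X)
  pnames <- c(tdes$names, colnames(X))
  dimnames(vcov) <- list(pnames, pnames)

  spline <- rcs_log_time(knots$boundary_knots, knots$internal_knots, gamma)
  # monotonicity of the fitted log cumulative hazard over the observed range
  chk <- seq(min(logt), max(logt), length.out = 200)
  mono <- all(drop(spline_basis(chk, spline, derivative = TRUE) %*% gamma) > 0)
  if (!mono && !length(td))
    warning("fitted s(log t) is not monotone over the observed time range")

  structure(
    list(spline = spline, beta = beta, td = td, delta = delta,
         vcov = vcov, loglik = o$loglik, df = df, n = length(time),
         nevent = sum(event),
         convergence = list(iterations = unname(opt$counts[1]),
                            newton_iterations = iter_newton,
                            gradient_norm = gnorm),
         monotone = mono,
         formula = formula, terms = tt, assign = asgn,
         X = X, time = time, event = event, data = data),
    class = "flexpar"
  )
}

#' @export
print.flexpar <- function(x, ...) {
  cat("Flexible parametric survival model (spline on log cumulative hazard)\n")
  cat("  n =", x$n, " events =", x$nevent, " spline df =", x$df, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " (gradient norm ", format(x$convergence$gradient_norm, digits = 2),
      ")\n", sep = "")
  if (length(x$beta)) {
    cat("Coefficients (log-hazard scale):\n")
    print(round(x$beta, 4))
  } else cat("Baseline-only model (no covariates)\n")
  invisible(x)
}

#' @export
summary.flexpar <- function(object, ...) {
  hr <- hazard_ratios(object)
  print(object)
  if (nrow(hr)) {
    cat("\nHazard ratios:\n")
    print(hr, digits = 4)
  }
  invisible(hr)
}

# log-cumulative-hazard value for each subject at their own observed time,
# under the fitted model (including any td terms)
flexpar_eta_obs <- function(fit) {
  tdes <- flexpar_time_design(log(fit$time), fit$spline, fit$X, fit$td)
  s <- drop(tdes$B %*% c(fit$spline$gamma, fit$delta))
  lp <- if (length(fit$beta)) drop(fit$X %*% fit$beta) else 0
  s + lp
}

#' Likelihood-ratio test of nested fits
#'
#' @param nested,full [flexpar()] fits on the same data, the nested model's
#'   parameters a subset of the full model's (spline df may also grow).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "flexpar"), inherits(full, "flexpar"))
  if (nested$n != full$n || nested$nevent != full$nevent)
    stop("models were not fitted to the same data")
  if (!all(names(nested$beta) %in% names(full$beta)))
    stop("models are not nested: nested covariates ",
         paste(setdiff(names(nested$beta), names(full$beta)), collapse = ", "),
         " absent from the full model")
  k_nested <- length(nested$spline$gamma) + length(nested$delta) + length(nested$beta)
  k_full <- length(full$spline$gamma) + length(full$delta) + length(full$beta)
  df <- k_full - k_nested
  if (df < 0) stop("full model has fewer parameters than the nested model")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Choose the spline degrees of freedom
#'
#' Sequential likelihood-ratio testing over ascending candidate df: the
#' smallest candidate not rejected against the next larger one at `alpha`
#' is selected (ties break toward fewer knots).
#'
#' @inheritParams flexpar
#' @param candidates Ascending integer vector of candidate df values.
#' @param alpha Significance level for the sequential tests.
#' @return The selected df (integer).
#' @export
select_df <- function(formula, data, candidates = 1:3, alpha = 0.05) {
  candidates <- sort(unique(as.integer(candidates)))
  stopifnot(all(candidates >= 1))
  if (length(candidates) == 1L) return(candidates)
  fits <- lapply(candidates, function(d) flexpar(formula, data, df = d))
  for (i in seq_len(length(candidates) - 1L)) {
    p <- lr_test(fits[[i]], fits[[i + 1L]])$p_value
    if (p > alpha) return(candidates[i])
  }
  candidates[length(candidates)]
}

#' Backward covariate selection
#'
#' Iteratively refits the model dropping, at each round, the removable term
#' with the largest likelihood-ratio p-value above `alpha` (multi-level
#' factors and interaction blocks drop as whole terms; main effects stay
#' while an interaction involving them remains).  Deterministic given the
#' input column order.
#'
#' @inheritParams flexpar
#' @param alpha Retention threshold (terms with p <= alpha stay).
#' @return The final [flexpar()] fit, with a `removal_order` character
#'   vector attribute recording dropped terms in order.
#' @export
backward_select <- function(formula, data, df = 2, alpha = 0.05) {
  fit <- flexpar(formula, data, df = df)
  removed <- character(0)
  repeat {
    labs <- attr(stats::terms(fit$formula), "term.labels")
    if (!length(labs)) break
    droppable <- stats::drop.scope(stats::terms(fit$formula))
    if (!length(droppable)) break
    pvals <- vapply(droppable, function(tm) {
      f_red <- stats::update(fit$formula, paste(". ~ . -", tm))
      red <- flexpar(f_red, data, df = df, knots = list(
        boundary_knots = fit$spline$boundary_knots,
        internal_knots = fit$spline$internal_knots))
      lr_test(red, fit)$p_value
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= alpha) break
    tm <- droppable[worst]
    removed <- c(removed, tm)
    fit <- flexpar(stats::update(fit$formula, paste(". ~ . -", tm)),
                   data, df = df)
  }
  attr(fit, "removal_order") <- removed
  fit
}

#' Test a time-dependent effect
#'
#' Augments the fitted proportional-hazards model with
#' covariate-by-spline-basis interaction terms for one covariate and
#' likelihood-ratio tests the augmented model against the proportional one
#' (a proportional-hazards adequacy check).
#'
#' @param fit A [flexpar()] fit.
#' @param covariate Design-matrix column name present in the fit.
#' @return The likelihood-ratio [lr_test()] result (list with `p_value`).
#' @export
test_td_effect <- function(fit, covariate) {
  stopifnot(inherits(fit, "flexpar"))
  if (!covariate %in% colnames(fit$X))
    stop("covariate '", covariate, "' is not in the fitted model")
  aug <- flexpar(fit$formula, fit$data, df = fit$df,
                 knots = list(boundary_knots = fit$spline$boundary_knots,
                              internal_knots = fit$spline$internal_knots),
                 td = unique(c(fit$td, covariate)))
  lr_test(fit, aug)
}

#' Martingale residuals
#'
#' `r_i = d_i - H_hat(t_i)`: the event indicator minus the fitted cumulative
#' hazard at the observed time.  They sum to near zero at the maximum
#' likelihood estimate and, smoothed against a continuous covariate, have
#' zero gradient when its functional form is adequate.
#'
#' @param fit A [flexpar()] fit.
#' @return Numeric residual vector, one per subject.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "flexpar"))
  fit$event - exp(flexpar_eta_obs(fit))
}

#' Functional-form check via residual regression
#'
#' Least-squares slope of Martingale residuals on a covariate; a slope more
#' than two standard errors from zero flags a mis-specified functional form
#' (e.g. a variable entered linearly that acts on the log scale).
#'
#' @param residuals Martingale residual vector.
#' @param covariate_values Covariate vector of the same length.
#' @return List with `slope`, `se`, and logical `flag`.
#' @export
functional_form_check <- function(residuals, covariate_values) {
  if (length(residuals) != length(covariate_values))
    stop("residuals and covariate_values must have equal length")
  if (length(residuals) < 3L)
    stop("need at least 3 observations")
  if (stats::sd(covariate_values) == 0)
    stop("covariate is constant; functional form cannot be assessed")
  fit <- stats::lm(residuals ~ covariate_values)
  sm <- summary(fit)$coefficients
  slope <- sm["covariate_values", "Estimate"]
  se <- sm["covariate_values", "Std. Error"]
  list(slope = slope, se = se, flag = abs(slope) / se > 2)
}

#' Hazard ratios with Wald intervals
#'
#' @param fit A [flexpar()] fit.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame with columns `term`, `coef`, `hr`, `lower`, `upper`,
#'   `p_value` (two-sided normal).
#' @export
hazard_ratios <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "flexpar"))
  if (!length(fit$beta))
    return(data.frame(term = character(0), coef = numeric(0),
                      hr = numeric(0), lower = numeric(0),
                      upper = numeric(0), p_value = numeric(0)))
  se <- sqrt(diag(fit$vcov)[names(fit$beta)])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    term = names(fit$beta),
    coef = unname(fit$beta),
    hr = exp(unname(fit$beta)),
    lower = exp(unname(fit$beta) - z * se),
    upper = exp(unname(fit$beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(fit$beta) / se)),
    row.names = NULL
  )
}

# design-matrix column name -> canonical PROSASH coefficient name
canonical_coef_names <- c(
  vascular_invasion = "vascular_invasion",
  age_centered = "age_centered",
  "vascular_invasion:age_centered" = "age_x_vi",
  "age_centered:vascular_invasion" = "age_x_vi",
  age_x_vi = "age_x_vi",
  ecog1 = "ecog1",
  ln_afp = "ln_afp",
  albumin = "albumin",
  ln_creatinine = "ln_creatinine",
  ln_ast = "ln_ast",
  ehs = "ehs",
  aetiologyHBV = "hbv",
  hbv = "hbv",
  aetiologyother = "other_aetiology",
  other_aetiology = "other_aetiology"
)

#' Convert a fit to a deployable model object
#'
#' Maps the fitted coefficients onto the PROSASH schema so any refitted
#' model plugs into the prediction engine and serialises to the same JSON.
#' Cutoffs default to the 15th/50th/85th centiles (type-1 inverse-ECDF
#' quantiles) of the linear predictor on the training data.
#'
#' @param fit A [flexpar()] fit on the canonical covariate structure
#'   (see [prosash_design()]).
#' @param cutoffs Optional explicit risk cutoffs; computed from the
#'   training-set linear predictor when `NULL`.
#' @param version Version tag for the serialised model.
#' @return A [prosash_model()].
#' @export
as_prosash_model <- function(fit, cutoffs = NULL, version = "refit") {
  stopifnot(inherits(fit, "flexpar"))
  if (length(fit$td))
    stop("models with time-dependent effects cannot be serialised to the proportional-hazards schema")
  nm <- names(fit$beta)
  unknown <- setdiff(nm, names(canonical_coef_names))
  if (length(unknown))
    stop("cannot map term(s) to the PROSASH schema: ",
         paste(unknown, collapse = ", "))
  coefs <- stats::setNames(unname(fit$beta), canonical_coef_names[nm])
  if (is.null(cutoffs)) {
    eta <- drop(fit$X %*% fit$beta)
    cutoffs <- unname(stats::quantile(eta, c(0.15, 0.50, 0.85), type = 1))
  }
  prosash_model(coefficients = coefs, spline = fit$spline, cutoffs = cutoffs,
                age_center = 60, version = version,
                follow_up_max = max(fit$time))
}

#' Canonical model-ready design from a raw cohort
#'
#' Builds the transformed analysis columns the PROSASH structure uses:
#' centred age, natural logs of AFP/creatinine/AST, 0/1 flags and the
#' aetiology factor (HCV reference), carrying `time` and `event` through
#' when present.
#'
#' @param cohort Data frame with the raw covariate columns (see
#'   [validate_covariates()]) and optionally `time`, `event`.
#' @param age_center Centring age in years.
#' @return Data frame ready for [flexpar()] with [prosash_formula()].
#' @export
prosash_design <- function(cohort, age_center = 60) {
  cov <- validate_covariates(cohort)
  out <- data.frame(
    vascular_invasion = cov$vascular_invasion,
    age_centered = cov$age - age_center,
    ecog1 = cov$ecog,
    ln_afp = log(cov$afp),
    albumin = cov$albumin,
    ln_creatinine = log(cov$creatinine),
    ln_ast = log(cov$ast),
    ehs = cov$ehs,
    aetiology = cov$aetiology
  )
  if (!is.null(cohort$time)) out$time <- cohort$time
  if (!is.null(cohort$event)) out$event <- cohort$event
  out
}

#' The canonical PROSASH model formula
#'
#' @param interaction Include the age-by-vascular-invasion interaction.
#' @return A formula for [flexpar()] on a [prosash_design()] frame.
#' @export
prosash_formula <- function(interaction = TRUE) {
  rhs <- if (interaction) "vascular_invasion * age_centered" else
    "vascular_invasion + age_centered"
  stats::as.formula(paste(
    "survival::Surv(time, event) ~", rhs,
    "+ ecog1 + ln_afp + albumin + ln_creatinine + ln_ast + ehs + aetiology"))
}
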