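test_that("knot placement follows the centile convention on uncensored log times", {
  # events spanning the published boundary with the published median
  time <- exp(c(-1.017, 1.0, 1.833, 2.5, 3.443))
  event <- rep(1, 5)
  k <- place_knots(time, event, df = 2)
  expect_equal(k$boundary_knots, c(-1.017, 3.443))
  expect_equal(k$internal_knots, 1.833)
  # df = 1: boundary knots only (Weibull-equivalent basis {1, log t})
  k1 <- place_knots(time, event, df = 1)
  expect_length(k1$internal_knots, 0)
  # censored times do not move the knots
  k2 <- place_knots(c(time, 40, 50), c(event, 0, 0), df = 2)
  expect_equal(k2, k)
  expect_error(place_knots(c(1, 1, 1), c(1, 1, 1), df = 2), "distinct")
})

test_that("the likelihood matches the closed-form Weibull oracle at df = 1", {
  time <- c(2.5, 7, 13); event <- c(1, 0, 1); x <- c(0, 1, 0)
  knots <- list(boundary_knots = log(c(2.5, 13)), internal_knots = numeric(0))
  for (pars in list(c(-2, 1.3, 0.4), c(-1, 0.8, -0.2), c(-3, 2.1, 0))) {
    gamma <- pars[1:2]; beta <- pars[3]
    # s(log t) = g0 + g1 log t  <=>  Weibull with shape g1, scale exp(-g0/g1)
    oracle <- weibull_loglik_oracle(a = gamma[2], b = exp(-gamma[1] / gamma[2]),
                                    beta = beta, time, event, x)
    mine <- flexpar_loglik(gamma, beta, time, event, X = cbind(x = x), knots)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("all-censored data contribute only the cumulative-hazard terms", {
  time <- c(1, 4, 9); event <- c(0, 0, 0)
  knots <- list(boundary_knots = c(0, 2.2), internal_knots = numeric(0))
  gamma <- c(-1.5, 1.1)
  s <- gamma[1] + gamma[2] * log(time)
  expect_equal(flexpar_loglik(gamma, numeric(0), time, event, NULL, knots),
               -sum(exp(s)), tolerance = 1e-12)
  # negative spline slope at an event time gives -Inf, not an error
  expect_identical(
    flexpar_loglik(c(0, -1), numeric(0), time, c(1, 0, 0), NULL, knots),
    -Inf)
})

test_that("perturbing parameters at the MLE decreases the likelihood", {
  dat <- toy_cohort(n = 150, seed = 3)
  fit <- flexpar(survival::Surv(time, event) ~ x, dat, df = 1)
  knots <- list(boundary_knots = fit$spline$boundary_knots,
                internal_knots = fit$spline$internal_knots)
  ll_hat <- flexpar_loglik(fit$spline$gamma, fit$beta, dat$time, dat$event,
                           cbind(x = dat$x), knots)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-8)
  set.seed(4)
  for (k in 1:10) {
    eps <- rnorm(3, 0, 0.05)
    ll <- flexpar_loglik(fit$spline$gamma + eps[1:2], fit$beta + eps[3],
                         dat$time, dat$event, cbind(x = dat$x), knots)
    expect_lt(ll, ll_hat + 1e-10)
  }
})

test_that("the fit agrees with an independent spline-model implementation", {
  skip_if_not_installed("flexsurv")
  dat <- toy_cohort(n = 300, seed = 8)
  fit <- flexpar(survival::Surv(time, event) ~ x, dat, df = 2)
  ref <- flexsurv::flexsurvspline(survival::Surv(time, event) ~ x, data = dat,
                                  k = 1, knots = fit$spline$internal_knots,
                                  bknots = fit$spline$boundary_knots)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$beta["x"]), unname(ref$res["x", "est"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$spline$gamma),
               unname(ref$res[c("gamma0", "gamma1", "gamma2"), "est"]),
               tolerance = 1e-4)
})

test_that("a null-model fit tracks the Kaplan-Meier estimate", {
  set.seed(5)
  n <- 400
  t_ev <- rweibull(n, shape = 1.3, scale = 9)
  time <- pmin(t_ev, 25); event <- as.integer(t_ev <= 25)
  dat <- data.frame(time = time, event = event)
  fit <- flexpar(survival::Surv(time, event) ~ 1, dat, df = 2)
  km <- kaplan_meier(time, event)
  at <- quantile(time, seq(0.1, 0.9, by = 0.1))
  s_fit <- baseline_survival(at, fit$spline)
  s_km <- vapply(at, function(tt) {
    idx <- which(km$time <= tt); if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
  expect_true(all(abs(s_fit - s_km) < 0.03))
  expect_true(all(diff(baseline_survival(seq(0.5, 25, by = 0.5), fit$spline)) <= 0))
})

test_that("a null-effect covariate is estimated near zero", {
  hits <- 0
  for (seed in 1:12) {
    dat <- toy_cohort(n = 120, seed = 100 + seed, beta = 0)
    fit <- flexpar(survival::Surv(time, event) ~ x, dat, df = 1)
    se <- sqrt(fit$vcov["x", "x"])
    if (abs(fit$beta["x"]) < 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 11)
})

test_that("fitting recovers the generating coefficients from a simulated cohort", {
  m <- published_model()
  dat <- generate_cohort(cohort_config(n = 2000, seed = 7), m)
  fit <- flexpar(prosash_formula(), prosash_design(dat), df = 2)
  truth <- c(vascular_invasion = 0.327, age_centered = -0.0231,
             ecog1 = 0.455, ln_afp = 0.0831, albumin = -0.0553,
             ln_creatinine = 0.709, ln_ast = 0.349, ehs = 0.298,
             aetiologyHBV = 0.526, aetiologyother = 0.507,
             "vascular_invasion:age_centered" = 0.0303)
  se <- sqrt(diag(fit$vcov)[names(truth)])
  expect_true(all(abs(fit$beta[names(truth)] - truth) < 3 * se))
})

test_that("likelihood-ratio tests behave on identical, nested and malformed pairs", {
  dat <- toy_cohort(n = 150, seed = 9)
  full <- flexpar(survival::Surv(time, event) ~ x, dat, df = 1)
  null <- flexpar(survival::Surv(time, event) ~ 1, dat, df = 1,
                  knots = list(boundary_knots = full$spline$boundary_knots,
                               internal_knots = numeric(0)))
  expect_equal(lr_test(full, full)$p_value, 1)
  lr <- lr_test(null, full)
  expect_equal(lr$df, 1)
  expect_equal(lr$p_value, pchisq(lr$statistic, 1, lower.tail = FALSE))
  # the chi-square quantile arithmetic: 2*delta = 3.841 on 1 df -> p = 0.05
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-5)
  expect_error(lr_test(full, null), "not nested")
})

test_that("spline df selection prefers the generating complexity", {
  # Weibull data: df = 1 should usually suffice
  picks1 <- vapply(1:5, function(s) {
    dat <- toy_cohort(n = 300, seed = 200 + s)
    select_df(survival::Surv(time, event) ~ x, dat, candidates = 1:2)
  }, numeric(1))
  expect_gte(sum(picks1 == 1), 3)
  expect_equal(select_df(survival::Surv(time, event) ~ x,
                         toy_cohort(n = 100, seed = 1), candidates = 2), 2)
})

test_that("backward selection drops null covariates and keeps active ones", {
  m <- published_model()
  hits <- 0
  for (seed in 1:3) {
    set.seed(300 + seed)
    dat <- generate_cohort(cohort_config(n = 1000, seed = 300 + seed), m)
    des <- prosash_design(dat)[, c("ecog1", "albumin", "time", "event")]
    des$junk <- rnorm(nrow(des))
    fit <- backward_select(survival::Surv(time, event) ~ ecog1 + albumin + junk,
                           des, df = 2, alpha = 0.05)
    kept <- names(fit$beta)
    if (!"junk" %in% kept && all(c("ecog1", "albumin") %in% kept))
      hits <- hits + 1
  }
  expect_gte(hits, 2)
  # alpha = 1 returns the full model untouched
  dat <- toy_cohort(n = 120, seed = 5)
  fit_full <- backward_select(survival::Surv(time, event) ~ x, dat,
                              df = 1, alpha = 1)
  expect_equal(names(fit_full$beta), "x")
  expect_length(attr(fit_full, "removal_order"), 0)
  # no covariates: the null model comes back
  fit_null <- backward_select(survival::Surv(time, event) ~ 1, dat, df = 1)
  expect_length(fit_null$beta, 0)
})

test_that("time-dependent effect testing flags built-in non-proportionality", {
  # group with crossing hazards: opposite Weibull shapes
  set.seed(17)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  t_ev <- ifelse(x == 1, rweibull(n, 0.6, 10), rweibull(n, 1.8, 10))
  time <- pmin(t_ev, 30); event <- as.integer(t_ev <= 30)
  dat <- data.frame(time = time, event = event, x = x)
  fit <- flexpar(survival::Surv(time, event) ~ x, dat, df = 2)
  expect_lt(test_td_effect(fit, "x")$p_value, 0.05)
  # proportional data should usually not be flagged
  datp <- toy_cohort(n = 400, seed = 18)
  fitp <- flexpar(survival::Surv(time, event) ~ x, datp, df = 2)
  expect_gt(test_td_effect(fitp, "x")$p_value, 0.001)
  expect_error(test_td_effect(fitp, "absent"), "not in the fitted model")
})

test_that("Martingale residuals sum to zero at the MLE and bound correctly", {
  dat <- toy_cohort(n = 300, seed = 21)
  fit <- flexpar(survival::Surv(time, event) ~ 1, dat, df = 2)
  r <- martingale_residuals(fit)
  expect_lt(abs(sum(r)), 1e-6 * nrow(dat))
  expect_true(all(r <= 1))
  # slope of residuals on a correctly specified covariate is within 2 SE of 0
  fitx <- flexpar(survival::Surv(time, event) ~ x, dat, df = 2)
  ffc <- functional_form_check(martingale_residuals(fitx), dat$x)
  expect_false(ffc$flag)
})

test_that("functional-form check flags a mis-specified covariate scale", {
  # The score equation forces residuals orthogonal to the covariate as
  # modelled, so the check is run against the candidate alternative form:
  # when the truth is log-scale but the model is linear, residuals
  # regressed on log(z) show a non-zero slope.
  set.seed(23)
  flags_wrong <- 0; flags_right <- 0
  for (s in 1:3) {
    n <- 2000
    z <- rlnorm(n, 0, 1.2)                 # acts through log(z)
    t_ev <- rexp(n, rate = 0.05 * exp(0.8 * log(z)))
    time <- pmin(t_ev, 60); event <- as.integer(t_ev <= 60)
    dat <- data.frame(time = time, event = event, z = z, lz = log(z))
    fit_lin <- flexpar(survival::Surv(time, event) ~ z, dat, df = 2)
    if (functional_form_check(martingale_residuals(fit_lin), dat$lz)$flag)
      flags_wrong <- flags_wrong + 1
    fit_log <- flexpar(survival::Surv(time, event) ~ lz, dat, df = 2)
    if (functional_form_check(martingale_residuals(fit_log), dat$lz)$flag)
      flags_right <- flags_right + 1
  }
  expect_gte(flags_wrong, 2)
  expect_lte(flags_right, 1)
  expect_error(functional_form_check(c(0.1, -0.1), c(1, 2)), "at least 3")
  expect_error(functional_form_check(c(0.1, -0.1, 0), c(1, 1, 1)), "constant")
})

test_that("hazard ratio tables exponentiate coefficients with Wald intervals", {
  dat <- toy_cohort(n = 250, seed = 25, beta = 0.7)
  fit <- flexpar(survival::Surv(time, event) ~ x, dat, df = 1)
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr, exp(hr$coef), tolerance = 1e-12)
  se <- sqrt(fit$vcov["x", "x"])
  expect_equal(hr$lower, exp(hr$coef - 1.96 * se), tolerance = 1e-3)
  # the published coefficient-to-HR arithmetic
  expect_equal(exp(0.327), 1.387, tolerance = 5e-4)
  expect_equal(exp(0.455), 1.576, tolerance = 5e-4)
})

test_that("rescaling the time unit leaves effects and likelihood differences unchanged", {
  dat <- toy_cohort(n = 250, seed = 27)
  dat_y <- transform(dat, time = time / 12)
  f_full <- survival::Surv(time, event) ~ x
  f_null <- survival::Surv(time, event) ~ 1
  fit_m <- flexpar(f_full, dat, df = 2)
  fit_y <- flexpar(f_full, dat_y, df = 2)
  expect_equal(fit_m$beta, fit_y$beta, tolerance = 1e-6)
  null_m <- flexpar(f_null, dat, df = 2)
  null_y <- flexpar(f_null, dat_y, df = 2)
  expect_equal(fit_m$loglik - null_m$loglik, fit_y$loglik - null_y$loglik,
               tolerance = 1e-6)
  expect_equal(hazard_ratios(fit_m)$hr, hazard_ratios(fit_y)$hr,
               tolerance = 1e-6)
})

test_that("fits serialise to the deployable schema and back", {
  m <- published_model()
  dat <- generate_cohort(cohort_config(n = 500, seed = 31), m)
  fit <- flexpar(prosash_formula(), prosash_design(dat), df = 2)
  refit <- as_prosash_model(fit, version = "refit-test")
  expect_s3_class(refit, "prosash_model")
  expect_setequal(names(refit$coefficients), names(m$coefficients))
  # cutoffs are the 15/50/85 type-1 centiles of the training linear predictor
  eta <- drop(fit$X %*% fit$beta)
  expect_equal(refit$cutoffs, unname(quantile(eta, c(0.15, 0.5, 0.85), type = 1)))
  # refitted model drives the prediction engine
  expect_true(all(is.finite(linear_predictor(dat, refit))))
  path <- tempfile(fileext = ".json")
  write_model_json(refit, path)
  expect_equal(read_model_json(path)$coefficients, refit$coefficients)
  unlink(path)
})
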