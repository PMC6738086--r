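test_that("Kaplan-Meier matches hand-computed product-limit values", {
  # 5-row toy with one censored subject
  times <- c(2, 3, 3, 5, 8); events <- c(1, 1, 1, 0, 1)
  km <- kaplan_meier(times, events)
  # hand product of (1 - d/n): t=2 -> 4/5; t=3 -> 4/5 * 2/4; t=8 -> 2/5 * 0
  expect_equal(km_at <- prosash:::km_survival_at(km, c(2, 3, 5, 8)),
               c(4 / 5, 4 / 5 * 2 / 4, 0.4, 0))
  # no censoring reduces to the empirical survival function
  t2 <- c(1, 4, 6, 9); km2 <- kaplan_meier(t2, rep(1, 4))
  expect_equal(prosash:::km_survival_at(km2, c(1, 4, 6, 9)),
               c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1, median not reached
  km3 <- kaplan_meier(c(3, 7), c(0, 0))
  expect_equal(prosash:::km_survival_at(km3, 10), 1)
  expect_true(is.na(km3$median))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier equals the product-limit oracle on exhaustive censoring patterns", {
  # 5 rows; each row independently takes one of 3 states (event at its own
  # time, censored at its own time, or a tied event at t = 3): 3^5 patterns
  base_times <- c(1, 2, 3, 4, 5)
  eval_at <- c(0.5, 1, 2, 3, 4, 5, 6)
  states <- expand.grid(rep(list(1:3), 5))
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    times <- ifelse(st == 3, 3, base_times)
    events <- ifelse(st == 2, 0L, 1L)
    if (sum(events) == 0) next
    km <- kaplan_meier(times, events)
    expect_equal(prosash:::km_survival_at(km, eval_at),
                 product_limit_oracle(times, events, eval_at),
                 tolerance = 1e-12)
  }
})

test_that("group hazard ratios recover known contrasts and invert under relabelling", {
  set.seed(33)
  n <- 500
  grp <- rep(c("a", "b"), each = n)
  t_ev <- c(rexp(n, 0.08), rexp(n, 0.16))   # true HR 2 for b vs a
  time <- pmin(t_ev, 30); event <- as.integer(t_ev <= 30)
  hr_ab <- group_hazard_ratio(time, event, grp, reference = "a")
  expect_true(hr_ab$hr[2] > 1.6 && hr_ab$hr[2] < 2.5)
  hr_ba <- group_hazard_ratio(time, event, grp, reference = "b")
  expect_equal(hr_ab$hr[2], 1 / hr_ba$hr[hr_ba$category == "a"],
               tolerance = 1e-9)
  # identical groups: HR near 1
  set.seed(34)
  t2 <- rexp(2 * n, 0.1); tm <- pmin(t2, 25); ev <- as.integer(t2 <= 25)
  hr_eq <- group_hazard_ratio(tm, ev, grp)
  expect_equal(hr_eq$hr[2], 1, tolerance = 0.2)
  # a category without events is flagged, not fatal
  t3 <- c(rexp(50, 0.2), runif(10, 20, 30))
  ev3 <- c(rep(1, 50), rep(0, 10))
  g3 <- c(rep("a", 25), rep("b", 25), rep("c", 10))
  hr3 <- group_hazard_ratio(pmin(t3, 31), ev3, g3, reference = "a")
  expect_true(hr3$infinite_ci[hr3$category == "c"])
})

test_that("the predicted mean survival curve averages member curves", {
  m <- published_model()
  pt <- worked_patient()
  grid <- c(3, 6, 12, 18, 24)
  one <- predicted_mean_survival(pt, m, grid)
  expect_equal(one$surv, survival_curve(pt, m, grid)$survival,
               tolerance = 1e-12)
  two <- rbind(pt, null_patient())
  pm <- predicted_mean_survival(two, m, grid)
  s_each <- cbind(survival_curve(pt, m, grid)$survival,
                  survival_curve(null_patient(), m, grid)$survival)
  expect_equal(pm$surv, rowMeans(s_each), tolerance = 1e-12)
  expect_error(predicted_mean_survival(pt[0, ], m, grid), "empty")
})

test_that("the cohort mean curve differs from the curve at the mean linear predictor as Jensen predicts", {
  # S(eta) = exp(-H0 exp(eta)) is convex in eta only where H0 exp(eta) > 1
  # (S < 1/e), concave where H0 exp(eta) < 1; Jensen's inequality therefore
  # puts the mean curve above the curve-at-mean-eta late in follow-up and
  # below it early on.
  m <- published_model()
  high_risk <- worked_patient(); high_risk$vascular_invasion <- 1
  dat <- rbind(worked_patient(), high_risk)
  eta <- linear_predictor(dat, m)
  grid <- c(0.5, 1, 2, 4, 50, 65, 80)
  pm <- predicted_mean_survival(dat, m, grid)
  at_mean <- baseline_survival(grid, m$spline)^exp(mean(eta))
  H0 <- exp(spline_log_cum_hazard(grid, m$spline))
  convex <- H0 * exp(min(eta)) > 1     # every member in the convex regime
  concave <- H0 * exp(max(eta)) < 1    # every member in the concave regime
  expect_gt(sum(convex), 0); expect_gt(sum(concave), 0)
  expect_true(all(pm$surv[convex] >= at_mean[convex] - 1e-12))
  expect_true(all(pm$surv[concave] <= at_mean[concave] + 1e-12))
})

test_that("centile-mode risk tables split an n = 500 cohort 75/175/175/75", {
  m <- published_model()
  dat <- generate_cohort(cohort_config(n = 500, seed = 41), m)
  rt <- build_risk_table(dat, m, mode = "centile")
  expect_equal(rt$n, c(75L, 175L, 175L, 75L))
  expect_equal(sum(rt$n), 500L)
})

test_that("risk tables are calibrated and ordered on model-generated cohorts", {
  m <- published_model()
  dat <- generate_cohort(cohort_config(n = 1000, seed = 43), m)
  rt <- build_risk_table(dat, m, mode = "published")
  occupied <- rt$n > 0
  gap <- abs(rt$observed_surv_at - rt$predicted_surv_at)[occupied]
  expect_true(all(gap < 8))   # single-seed check; the multi-seed average is tighter
  med <- rt$observed_median
  med[is.na(med)] <- Inf      # not-reached sorts worst-case high
  expect_true(all(diff(med) <= 0))
  expect_equal(rt$hr[1], 1)
  expect_true(all(diff(rt$hr[occupied]) > 0))
})

test_that("degenerate cohorts collapse into a single occupied category", {
  m <- published_model()
  pt <- worked_patient()[rep(1, 30), ]
  pt$time <- seq(1, 30); pt$event <- 1
  rt <- build_risk_table(pt, m, mode = "published")
  expect_equal(sum(rt$n > 0), 1L)
  expect_true(all(is.na(rt$observed_median[rt$n == 0])))
})
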