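#' Kaplan-Meier curve with Greenwood intervals
#'
#' Product-limit estimate of the survival function with pointwise 95%
#' confidence limits on the log(-log) scale (Greenwood variance) and the
#' median with its Brookmeyer-Crowley interval from the confidence-band
#' crossing.  A median (or CI limit) whose crossing of 50% survival never
#' occurs is reported as `NA` - the "not reached" sentinel.
#'
#' @param times Observed times in months, strictly positive.
#' @param events Event indicators (1 = death).
#' @param conf_level Confidence level.
#' @return List of class `"km_curve"`: `time`, `surv`, `lower`, `upper`,
#'   `n_risk`, `n_event`, `variance` (Greenwood), `median`, `median_ci`,
#'   `n`, `nevent`.
#' @export
kaplan_meier <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0) stop("empty input")
  if (any(times <= 0)) stop("times must be strictly positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(q$quantile)
  med_ci <- c(unname(q$lower), unname(q$upper))
  structure(
    list(time = fit$time, surv = fit$surv,
         lower = fit$lower, upper = fit$upper,
         n_risk = fit$n.risk, n_event = fit$n.event,
         variance = fit$std.err^2 * fit$surv^2,  # Greenwood, survival scale
         median = med, median_ci = med_ci,
         n = fit$n, nevent = sum(fit$n.event)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, " events =", x$nevent, "\n")
  cat(sprintf("  median %s months (95%% CI %s, %s)\n",
              format(x$median, digits = 4),
              format(x$median_ci[1], digits = 4),
              format(x$median_ci[2], digits = 4)))
  invisible(x)
}

# step-function evaluation of a km_curve at arbitrary times
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Hazard ratios between patient groups
#'
#' Fits a single-factor flexible parametric model (df = 2 spline baseline)
#' to the grouped data and reports each category's hazard ratio against the
#' reference with Wald intervals.  A category without events is reported
#' with an infinite-interval flag rather than an error.
#'
#' @param times,events Survival outcome.
#' @param categories Group labels (coercible to factor).
#' @param reference Reference level (default the first).
#' @param df Spline df of the underlying fit.
#' @return Data frame: `category`, `n`, `events`, `hr`, `lower`, `upper`,
#'   `p_value`, `infinite_ci` flag.
#' @export
group_hazard_ratio <- function(times, events, categories, reference = NULL,
                               df = 2) {
  f <- factor(categories)
  if (!is.null(reference)) f <- stats::relevel(f, ref = as.character(reference))
  if (nlevels(f) < 2) stop("need at least two categories")
  lev <- levels(f)
  ev_by <- tapply(events, f, sum)
  ev_by[is.na(ev_by)] <- 0
  if (sum(ev_by > 0) < 2) stop("need events in at least two categories")
  if (ev_by[1] == 0)
    stop("reference category has no events; choose another reference")
  with_events <- lev[ev_by > 0]
  keep <- f %in% with_events
  dat <- data.frame(time = times[keep], event = events[keep],
                    grp = factor(as.character(f[keep]), levels = with_events))
  fit <- flexpar(survival::Surv(time, event) ~ grp, dat, df = df)
  hr <- hazard_ratios(fit)
  out <- data.frame(
    category = lev,
    n = as.integer(table(f)),
    events = as.integer(ev_by[lev]),
    hr = NA_real_, lower = NA_real_, upper = NA_real_, p_value = NA_real_,
    infinite_ci = FALSE
  )
  out$hr[1] <- 1
  for (k in seq_along(lev)[-1]) {
    if (ev_by[lev[k]] == 0) {          # no deaths: HR unidentified
      out$infinite_ci[k] <- TRUE
      next
    }
    row <- hr[hr$term == paste0("grp", lev[k]), ]
    out$hr[k] <- row$hr; out$lower[k] <- row$lower
    out$upper[k] <- row$upper; out$p_value[k] <- row$p_value
    if (!is.finite(row$upper) || row$upper / max(row$lower, 1e-300) > 1e6)
      out$infinite_ci[k] <- TRUE
  }
  out
}

#' Model-predicted mean survival curve of a cohort
#'
#' The pointwise arithmetic mean of the members' individual survival
#' curves S_i(t) - the "model-predicted mean survival" overlaid on observed
#' Kaplan-Meier curves in calibration plots.  (This differs from the curve
#' of the mean linear predictor: by convexity the mean of curves lies
#' above it.)
#'
#' @param cohort Covariate data.frame (one row per patient).
#' @param model A [prosash_model()].
#' @param grid Ascending positive times in months.
#' @return List of class `"mean_survival_curve"`: `time`, `surv`,
#'   `median` (first grid crossing of 0.5, `NA` if none) and
#'   `surv12` (mean survival at 12 months, a probability).
#' @export
predicted_mean_survival <- function(cohort, model = published_model(), grid) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (any(grid <= 0) || is.unsorted(grid)) stop("grid must be positive ascending")
  eta <- linear_predictor(cohort, model)
  s0 <- baseline_survival(grid, model$spline)
  surv <- rowMeans(outer(s0, exp(eta), `^`))
  cross <- which(surv <= 0.5)
  med <- if (length(cross)) grid[min(cross)] else NA_real_
  s12 <- mean(baseline_survival(12, model$spline)^exp(eta))
  structure(list(time = grid, surv = surv, median = med, surv12 = s12),
            class = "mean_survival_curve")
}

#' Risk-group calibration table
#'
#' Assigns each patient a risk category - from the model's published cutoffs
#' (validation use) or from the 15th/50th/85th centiles of the linear
#' predictor computed on this cohort (training use) - and tabulates, per
#' category: N, observed median survival with CI, model-predicted median,
#' observed and predicted percentage survival at 12 months, and hazard
#' ratios versus category 1.  Empty categories yield NA rows.
#'
#' @param data Data frame with covariate columns plus `time` (months) and
#'   `event`.
#' @param model A [prosash_model()].
#' @param mode `"published"` uses `model$cutoffs`; `"centile"` recomputes
#'   cutoffs as type-1 quantiles of eta on this cohort.
#' @param at Months at which percentage survival is reported (default 12).
#' @param horizon Months; grid limit for the predicted median search.
#' @return Data frame of class `"risk_table"`, one row per category 1-4,
#'   with the cutoffs used and category assignment attached as attributes.
#' @export
build_risk_table <- function(data, model = published_model(),
                             mode = c("published", "centile"),
                             at = 12, horizon = 60) {
  mode <- match.arg(mode)
  stopifnot(all(c("time", "event") %in% names(data)))
  eta <- linear_predictor(data, model)
  cutoffs <- if (mode == "published") model$cutoffs else
    unname(stats::quantile(eta, c(0.15, 0.50, 0.85), type = 1))
  cat4 <- risk_category(eta, cutoffs)
  grid <- seq(0.05, horizon, by = 0.05)
  out <- data.frame(category = 1:4, n = 0L,
                    observed_median = NA_real_,
                    observed_median_lower = NA_real_,
                    observed_median_upper = NA_real_,
                    predicted_median = NA_real_,
                    observed_surv_at = NA_real_,
                    observed_surv_at_lower = NA_real_,
                    observed_surv_at_upper = NA_real_,
                    predicted_surv_at = NA_real_,
                    hr = NA_real_, hr_lower = NA_real_, hr_upper = NA_real_,
                    hr_p = NA_real_)
  for (k in 1:4) {
    sel <- cat4 == k
    out$n[k] <- sum(sel)
    if (!any(sel)) next
    km <- kaplan_meier(data$time[sel], data$event[sel])
    out$observed_median[k] <- km$median
    out$observed_median_lower[k] <- km$median_ci[1]
    out$observed_median_upper[k] <- km$median_ci[2]
    idx <- which(km$time <= at)
    out$observed_surv_at[k] <- 100 * km_survival_at(km, at)
    if (length(idx)) {
      last <- max(idx)
      out$observed_surv_at_lower[k] <- 100 * km$lower[last]
      out$observed_surv_at_upper[k] <- 100 * km$upper[last]
    } else {
      out$observed_surv_at_lower[k] <- 100
      out$observed_surv_at_upper[k] <- 100
    }
    pm <- predicted_mean_survival(data[sel, , drop = FALSE], model, grid)
    out$predicted_median[k] <- pm$median
    out$predicted_surv_at[k] <- 100 *
      mean(baseline_survival(at, model$spline)^exp(eta[sel]))
  }
  occupied <- which(out$n > 0 & tapply(data$event, factor(cat4, 1:4), sum) > 0)
  if (length(occupied) >= 2) {
    ghr <- group_hazard_ratio(data$time[cat4 %in% occupied],
                              data$event[cat4 %in% occupied],
                              cat4[cat4 %in% occupied],
                              reference = min(occupied))
    for (r in seq_len(nrow(ghr))) {
      k <- as.integer(as.character(ghr$category[r]))
      out$hr[k] <- ghr$hr[r]; out$hr_lower[k] <- ghr$lower[r]
      out$hr_upper[k] <- ghr$upper[r]; out$hr_p[k] <- ghr$p_value[r]
    }
  }
  attr(out, "cutoffs") <- cutoffs
  attr(out, "mode") <- mode
  attr(out, "category") <- cat4
  class(out) <- c("risk_table", "data.frame")
  out
}
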