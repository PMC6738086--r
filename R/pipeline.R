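#' Read a patient CSV with unit plausibility checks
#'
#' One canonical schema for all pipeline commands: columns named as in
#' [validate_covariates()] (age years, AFP ng/ml, albumin g/l, creatinine
#' umol/L, AST U/L) plus optional `time` (months) and `event` (0/1).
#' Unit drift is the main real-world failure mode for this model, so
#' implausible scales are hard errors, not warnings: ages outside 18-100,
#' non-positive lab values or times, times beyond 600 months (suggesting
#' days), or creatinine medians below 15 (suggesting mg/dl).
#'
#' @param path CSV file path.
#' @param require_outcome Demand `time` and `event` columns.
#' @return Validated data.frame.
#' @export
read_patient_csv <- function(path, require_outcome = FALSE) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0) return(data)
  data <- validate_covariates(data)
  if (require_outcome || all(c("time", "event") %in% names(data))) {
    if (!all(c("time", "event") %in% names(data)))
      stop("columns 'time' (months) and 'event' (0/1) are required")
    if (any(data$time <= 0)) stop("field 'time' must be positive months")
    if (max(data$time) > 600)
      stop("field 'time' exceeds 600: looks like days, expected months")
    if (!all(data$event %in% c(0, 1))) stop("field 'event' must be 0/1")
  }
  if (stats::median(data$creatinine) < 15)
    stop("field 'creatinine' median < 15: looks like mg/dl, expected umol/L")
  data
}

#' Batch prediction
#'
#' Applies a model to a patient CSV: per row the linear predictor, risk
#' category, survival probability at each requested time, and predicted
#' median survival.  An empty input yields a header-only output with a
#' warning.
#'
#' @param input Path to a covariate CSV ([read_patient_csv()] schema).
#' @param output Path for the predictions CSV; `NULL` returns the data
#'   frame without writing.
#' @param times Months at which survival probabilities are reported.
#' @param model A [prosash_model()] or path to a model JSON.
#' @return The predictions data.frame, invisibly when written.
#' @export
run_predict <- function(input, output = NULL, times = c(3, 6, 12, 18, 24),
                        model = published_model()) {
  if (is.character(model)) model <- read_model_json(model)
  stopifnot(all(times > 0))
  data <- read_patient_csv(input)
  if (nrow(data) == 0) {
    warning("empty input: writing header-only predictions")
    res <- data.frame(eta = numeric(0), risk_category = integer(0))
    for (tt in times) res[[paste0("surv_", tt, "m")]] <- numeric(0)
    res$predicted_median <- numeric(0)
  } else {
    eta <- linear_predictor(data, model)
    res <- data.frame(eta = eta, risk_category = risk_category(eta, model$cutoffs))
    s0 <- baseline_survival(times, model$spline)
    for (i in seq_along(times))
      res[[paste0("surv_", times[i], "m")]] <- s0[i]^exp(eta)
    res$predicted_median <- predicted_median_survival(data, model)
  }
  res <- cbind(data, res)
  if (is.null(output)) return(res)
  utils::write.csv(res, output, row.names = FALSE)
  invisible(res)
}

#' Simulate a cohort to CSV
#'
#' Writes a [generate_cohort()] dataset plus a sidecar JSON with the
#' provenance block (seed, config, model version, achieved event fraction).
#'
#' @param config A [cohort_config()].
#' @param output CSV path; the sidecar is `<output>.meta.json`.
#' @param model Generating model.
#' @return The dataset, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), output,
                         model = published_model()) {
  data <- generate_cohort(config, model)
  utils::write.csv(data, output, row.names = FALSE)
  prov <- attr(data, "provenance")
  prov$config <- config[setdiff(names(config), c("n", "seed"))]
  jsonlite::write_json(prov, paste0(output, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(data)
}

#' Fit the full modelling pipeline to a dataset
#'
#' Complete-case filtering, spline df selection by sequential LR test,
#' backward covariate selection at 5%, time-dependent-effect checks on the
#' retained covariates, and serialisation of the final model (and a fit
#' report) to JSON.
#'
#' @param input Path to a cohort CSV with outcome columns, or a data.frame.
#' @param model_out,report_out Optional JSON output paths.
#' @param candidates Candidate spline dfs.
#' @param alpha Backward-selection significance threshold.
#' @return List with `fit` (the final [flexpar()]), `model`
#'   ([prosash_model()] when the terms map onto the schema), `df`,
#'   `removal_order`, `td_p_values`, `n_dropped_incomplete`.
#' @export
run_fit <- function(input, model_out = NULL, report_out = NULL,
                    candidates = 1:3, alpha = 0.05) {
  data <- if (is.character(input)) read_patient_csv(input, require_outcome = TRUE)
          else input
  if (sum(data$event, na.rm = TRUE) == 0) stop("dataset has zero events")
  n0 <- nrow(data)
  des <- prosash_design(complete_cases(
    data, c(covariate_fields(), "time", "event")))
  n_dropped <- n0 - nrow(des)
  f <- prosash_formula()
  df_sel <- select_df(f, des, candidates = candidates)
  fit <- backward_select(f, des, df = df_sel, alpha = alpha)
  td_p <- vapply(colnames(fit$X), function(cv)
    test_td_effect(fit, cv)$p_value, numeric(1))
  model <- tryCatch(as_prosash_model(fit), error = function(e) NULL)
  if (!is.null(model_out) && !is.null(model)) write_model_json(model, model_out)
  report <- list(
    n = fit$n, events = fit$nevent, df = df_sel,
    loglik = fit$loglik, aic = -2 * fit$loglik +
      2 * (length(fit$beta) + length(fit$spline$gamma)),
    convergence = fit$convergence,
    removal_order = attr(fit, "removal_order"),
    td_p_values = as.list(td_p),
    n_dropped_incomplete = n_dropped
  )
  if (!is.null(report_out))
    jsonlite::write_json(report, report_out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  list(fit = fit, model = model, df = df_sel,
       removal_order = attr(fit, "removal_order"),
       td_p_values = td_p, n_dropped_incomplete = n_dropped)
}

#' Validate a model on a dataset
#'
#' Builds the risk-group calibration table (published cutoffs), the
#' discrimination summary (c-index, D, R2_D with seeded bootstrap CIs) and
#' long-format calibration curves (observed KM with confidence limits and
#' predicted mean survival per category).
#'
#' @param input Cohort CSV path or data.frame with outcome columns.
#' @param model A [prosash_model()] or model JSON path.
#' @param risk_table_out,discrimination_out,curves_out Optional output
#'   paths (CSV, JSON, CSV).
#' @param reps Bootstrap replicates (default 200).
#' @param seed Bootstrap seed.
#' @param grid Time grid (months) for the calibration curves.
#' @return List with `risk_table`, `discrimination`, `curves`.
#' @export
run_validate <- function(input, model = published_model(),
                         risk_table_out = NULL, discrimination_out = NULL,
                         curves_out = NULL, reps = 200, seed = 1,
                         grid = seq(0.5, 30, by = 0.5)) {
  if (is.character(model)) model <- read_model_json(model)
  data <- if (is.character(input)) read_patient_csv(input, require_outcome = TRUE)
          else input
  data <- complete_cases(data, c(covariate_fields(), "time", "event"))
  rt <- build_risk_table(data, model, mode = "published")
  eta <- linear_predictor(data, model)
  disc <- discrimination(data$time, data$event, eta, reps = reps, seed = seed)
  cat4 <- attr(rt, "category")
  curves <- do.call(rbind, lapply(sort(unique(cat4)), function(k) {
    sel <- cat4 == k
    km <- kaplan_meier(data$time[sel], data$event[sel])
    pm <- predicted_mean_survival(data[sel, , drop = FALSE], model, grid)
    data.frame(category = k, time = grid,
               observed_surv = km_survival_at(km, grid),
               observed_lower = stats::approx(km$time, km$lower, grid,
                                              method = "constant", rule = 2,
                                              yleft = 1)$y,
               observed_upper = stats::approx(km$time, km$upper, grid,
                                              method = "constant", rule = 2,
                                              yleft = 1)$y,
               predicted_surv = pm$surv)
  }))
  if (!is.null(risk_table_out))
    utils::write.csv(rt, risk_table_out, row.names = FALSE)
  if (!is.null(discrimination_out))
    jsonlite::write_json(
      list(c_index = disc$c_index, c_index_ci = disc$c_index_ci,
           D = disc$D, D_ci = disc$D_ci,
           r2_d = disc$r2_d, r2_d_ci = disc$r2_d_ci,
           reps = reps, seed = seed),
      discrimination_out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(curves_out))
    utils::write.csv(curves, curves_out, row.names = FALSE)
  list(risk_table = rt, discrimination = disc, curves = curves)
}
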