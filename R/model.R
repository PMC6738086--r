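#' PROSASH model object
#'
#' Bundles the components of a proportional-hazards flexible parametric
#' survival model on the log-cumulative-hazard scale: named log-hazard
#' coefficients, the baseline spline, risk-category cutoffs on the linear
#' predictor, and the age centring constant.  The published model ships with
#' the package (see [published_model()]); fitted models from [flexpar()] can
#' be converted with [as_prosash_model()] and used interchangeably.
#'
#' @param coefficients Named numeric vector of log-hazard-scale coefficients.
#'   For the nine-covariate PROSASH structure the names are
#'   `vascular_invasion`, `age_centered`, `age_x_vi`, `ecog1`, `ln_afp`,
#'   `albumin`, `ln_creatinine`, `ln_ast`, `ehs`, `hbv`, `other_aetiology`
#'   (HCV is the reference aetiology with implicit coefficient 0).
#' @param spline An [rcs_log_time()] object for s(log t).
#' @param cutoffs Three strictly increasing linear-predictor thresholds
#'   separating risk categories 1-4.
#' @param age_center Age (years) subtracted before applying the age terms.
#' @param version Free-text version tag carried into serialised output.
#' @param follow_up_max Months of observed follow-up behind the model;
#'   predictions past this horizon are extrapolations and are flagged.
#' @return An object of class `"prosash_model"`.
#' @export
prosash_model <- function(coefficients, spline, cutoffs,
                          age_center = 60, version = "unversioned",
                          follow_up_max = 31.28) {
  coefficients <- unlist(coefficients)
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be a fully named numeric vector")
  stopifnot(inherits(spline, "rcs_log_time"))
  cutoffs <- as.numeric(cutoffs)
  if (length(cutoffs) != 3L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be three strictly increasing values")
  structure(
    list(coefficients = coefficients, spline = spline, cutoffs = cutoffs,
         age_center = age_center, version = as.character(version),
         follow_up_max = follow_up_max),
    class = "prosash_model"
  )
}

#' @export
print.prosash_model <- function(x, ...) {
  cat("PROSASH-type survival model (version ", x$version, ")\n", sep = "")
  cat("Log-hazard coefficients:\n")
  print(round(x$coefficients, 4))
  print(x$spline)
  cat("Risk cutoffs on the linear predictor:",
      format(x$cutoffs, digits = 4), "\n")
  cat("Age centred at", x$age_center, "years\n")
  invisible(x)
}

#' The published PROSASH model
#'
#' Loads the published model constants (coefficients, spline knots and gamma,
#' risk cutoffs) from the versioned JSON asset shipped with the package.
#'
#' @return A [prosash_model()] object.
#' @export
#' @examples
#' m <- published_model()
#' baseline_survival(12, m$spline)   # 0.977
published_model <- function() {
  read_model_json(system.file("extdata", "prosash_model.json",
                              package = "prosash", mustWork = TRUE))
}

#' Read / write a model as JSON
#'
#' The JSON schema is the package's interchange format: published constants,
#' refitted models and the prediction engine all speak it.
#'
#' @param path File path.
#' @return `read_model_json()` returns a [prosash_model()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- rcs_log_time(doc$spline$boundary_knots,
                     doc$spline$internal_knots %||% numeric(0),
                     doc$spline$gamma)
  prosash_model(coefficients = doc$coefficients,
                spline = sp,
                cutoffs = doc$cutoffs,
                age_center = doc$age_center %||% 60,
                version = doc$version %||% "unversioned",
                follow_up_max = doc$follow_up_max_months %||% 31.28)
}

#' @rdname read_model_json
#' @param model A [prosash_model()] object.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    model = "PROSASH-type",
    version = model$version,
    age_center = model$age_center,
    coefficients = as.list(model$coefficients),
    aetiology_reference = "HCV",
    spline = list(boundary_knots = model$spline$boundary_knots,
                  internal_knots = model$spline$internal_knots,
                  gamma = model$spline$gamma),
    cutoffs = model$cutoffs,
    follow_up_max_months = model$follow_up_max
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# required covariate columns, in canonical order
covariate_fields <- function() {
  c("age", "vascular_invasion", "ecog", "afp", "albumin",
    "creatinine", "ast", "ehs", "aetiology")
}

#' Validate a patient covariate table
#'
#' Checks the nine PROSASH baseline covariates: presence, ranges and units.
#' Ages outside 18-100 years, non-positive AFP/creatinine/AST (their logs
#' enter the model), flags outside {0,1} and unknown aetiology levels are
#' hard errors naming the offending field; values are never clamped.
#'
#' @param cov A data.frame with columns `age` (years), `vascular_invasion`
#'   (0/1), `ecog` (0/1), `afp` (ng/ml), `albumin` (g/l), `creatinine`
#'   (umol/L), `ast` (U/L), `ehs` (0/1), `aetiology` ("HCV"/"HBV"/"other").
#' @return The validated data.frame, invisibly, with `aetiology` as a factor
#'   with levels HCV, HBV, other.
#' @export
validate_covariates <- function(cov) {
  missing_cols <- setdiff(covariate_fields(), names(cov))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  chk_flag <- function(field) {
    v <- cov[[field]]
    if (!all(v %in% c(0, 1)))
      stop("field '", field, "' must be 0/1")
  }
  chk_flag("vascular_invasion"); chk_flag("ecog"); chk_flag("ehs")
  if (any(cov$age < 18 | cov$age > 100))
    stop("field 'age' outside [18, 100] years; check units")
  for (field in c("afp", "creatinine", "ast")) {
    if (any(cov[[field]] <= 0))
      stop("field '", field, "' must be strictly positive (log-transformed); ",
           "apply a documented detection-limit floor upstream if needed")
  }
  ae <- as.character(cov$aetiology)
  if (!all(ae %in% c("HCV", "HBV", "other")))
    stop("field 'aetiology' must be one of HCV, HBV, other")
  cov$aetiology <- factor(ae, levels = c("HCV", "HBV", "other"))
  invisible(cov)
}

#' Linear predictor (prognostic index)
#'
#' eta = sum of coefficient x covariate terms on the log-hazard scale: age
#' centred at `age_center`, natural logs of AFP/creatinine/AST, the
#' age-by-vascular-invasion interaction applied only when vascular invasion
#' is present, HCV the reference aetiology.
#'
#' @param cov Covariate data.frame (see [validate_covariates()]).
#' @param model A [prosash_model()]; defaults to the published model.
#' @return Numeric vector of linear predictors, one per row.
#' @export
#' @examples
#' pt <- data.frame(age = 71, vascular_invasion = 0, ecog = 1, afp = 850.3,
#'                  albumin = 46, creatinine = 35.36, ast = 29, ehs = 0,
#'                  aetiology = "other")
#' linear_predictor(pt)   # 2.43
linear_predictor <- function(cov, model = published_model()) {
  cov <- validate_covariates(cov)
  b <- model$coefficients
  age_c <- cov$age - model$age_center
  vi <- cov$vascular_invasion
  eta <- b[["vascular_invasion"]] * vi +
    b[["age_centered"]] * age_c +
    b[["age_x_vi"]] * age_c * vi +
    b[["ecog1"]] * cov$ecog +
    b[["ln_afp"]] * log(cov$afp) +
    b[["albumin"]] * cov$albumin +
    b[["ln_creatinine"]] * log(cov$creatinine) +
    b[["ln_ast"]] * log(cov$ast) +
    b[["ehs"]] * cov$ehs +
    b[["hbv"]] * (cov$aetiology == "HBV") +
    b[["other_aetiology"]] * (cov$aetiology == "other")
  unname(eta)
}

#' Individual survival probability
#'
#' S(t) = S0(t)^exp(eta) for each patient row at each time.
#'
#' @inheritParams linear_predictor
#' @param t Time(s) in months, strictly positive.  Either a scalar, or a
#'   vector matching the number of rows of `cov`.
#' @return Survival probabilities.  Times beyond the model's observed
#'   follow-up carry an `"extrapolated"` attribute flag.
#' @export
survival_probability <- function(cov, t, model = published_model()) {
  eta <- linear_predictor(cov, model)
  s0 <- baseline_survival(t, model$spline)
  out <- s0^exp(eta)
  if (any(t > model$follow_up_max))
    attr(out, "extrapolated") <- t > model$follow_up_max
  out
}

#' Cumulative hazard for an individual
#'
#' H(t) = exp(s(log t) + eta) = -log S(t).
#'
#' @inheritParams survival_probability
#' @return Non-negative cumulative hazards.
#' @export
cumulative_hazard <- function(cov, t, model = published_model()) {
  eta <- linear_predictor(cov, model)
  exp(spline_log_cum_hazard(t, model$spline) + eta)
}

#' Risk category from the linear predictor
#'
#' Four ordered categories with closed upper bounds: eta <= c1 is category
#' 1, c1 < eta <= c2 category 2, c2 < eta <= c3 category 3, eta > c3
#' category 4.  The published cutoffs (2.898, 3.666, 4.559) are the
#' training-set 15th/50th/85th centiles of eta.
#'
#' @param eta Numeric vector of linear predictors (not rounded).
#' @param cutoffs Three ascending thresholds; default the published ones.
#' @return Integer vector in 1..4.
#' @export
risk_category <- function(eta, cutoffs = published_model()$cutoffs) {
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs, strictly = TRUE))
  findInterval(eta, cutoffs, left.open = TRUE) + 1L
}

#' Predicted median survival
#'
#' Smallest t with S(t) <= 0.5, located by monotone root-finding on log t.
#' If survival at the horizon still exceeds 0.5 the median is not reached
#' and `NA` is returned (the Table-3 "NA" sentinel).
#'
#' @inheritParams survival_probability
#' @param horizon Months; search limit, default the model's follow-up range.
#' @return Numeric vector of medians in months, `NA` where not reached.
#' @export
predicted_median_survival <- function(cov, model = published_model(),
                                      horizon = model$follow_up_max) {
  stopifnot(horizon > 0)
  eta <- linear_predictor(cov, model)
  # S(t) = 0.5  <=>  s(log t) = log(log 2) - eta
  target <- log(log(2)) - eta
  med <- spline_inverse(target, model$spline)
  med[med > horizon] <- NA_real_
  med
}

#' Individual survival curve on a time grid
#'
#' @inheritParams survival_probability
#' @param grid Ascending positive times (months).
#' @return A data.frame of class `"survival_curve"` with columns `time` and
#'   `survival` (plus one survival column per patient when `cov` has several
#'   rows, named `survival.1`, `survival.2`, ...).
#' @export
survival_curve <- function(cov, model = published_model(), grid) {
  if (length(grid) == 0)
    return(structure(data.frame(time = numeric(0), survival = numeric(0)),
                     class = c("survival_curve", "data.frame")))
  if (any(grid <= 0) || is.unsorted(grid))
    stop("grid must be positive and ascending")
  eta <- linear_predictor(cov, model)
  s0 <- baseline_survival(grid, model$spline)
  surv <- outer(s0, exp(eta), `^`)
  out <- data.frame(time = grid)
  if (ncol(surv) == 1L) out$survival <- surv[, 1] else {
    colnames(surv) <- paste0("survival.", seq_len(ncol(surv)))
    out <- cbind(out, surv)
  }
  structure(out, class = c("survival_curve", "data.frame"))
}
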