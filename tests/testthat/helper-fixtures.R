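# Shared fixtures and independent oracles for the test suite.

# The worked patient from the model's published example: elderly, ECOG 1,
# high AFP, good albumin/creatinine/AST, no spread or invasion, non-viral.
worked_patient <- function() {
  data.frame(age = 71, vascular_invasion = 0, ecog = 1, afp = 850.3,
             albumin = 46, creatinine = 35.36, ast = 29, ehs = 0,
             aetiology = "other", stringsAsFactors = FALSE)
}

# A patient whose linear predictor is exactly zero under the published
# coefficients (all terms vanish).
null_patient <- function() {
  data.frame(age = 60, vascular_invasion = 0, ecog = 0, afp = 1,
             albumin = 0, creatinine = 1, ast = 1, ehs = 0,
             aetiology = "HCV", stringsAsFactors = FALSE)
}

# Exhaustive O(n^2) pair-enumeration oracle for the concordance index,
# written independently of the package implementation.
c_index_oracle <- function(times, events, scores) {
  conc <- 0; ties <- 0; comp <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (events[i] == 1) &&
      (times[i] < times[j] || (times[i] == times[j] && events[j] == 0))
    if (!comparable) next
    comp <- comp + 1
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) ties <- ties + 1
  }
  if (comp == 0) return(NA_real_)
  (conc + 0.5 * ties) / comp
}

# Hand product-limit oracle: S(t) = prod over event times <= t of
# (1 - d_k / n_k) with n_k the number still at risk.
product_limit_oracle <- function(times, events, at) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(at))
  for (k in seq_along(at)) {
    s <- 1
    for (tt in ut[ut <= at[k]]) {
      d <- sum(times == tt & events == 1)
      n_risk <- sum(times >= tt)
      s <- s * (1 - d / n_risk)
    }
    out[k] <- s
  }
  out
}

# Closed-form right-censored Weibull log-likelihood (shape a, scale b,
# multiplicative covariate effect exp(x beta) on the hazard).
weibull_loglik_oracle <- function(a, b, beta, time, event, x) {
  H <- (time / b)^a * exp(x * beta)
  h <- (a / b) * (time / b)^(a - 1) * exp(x * beta)
  sum(event * log(h)) - sum(H)
}

# Small simulated survival dataset with one active binary covariate.
toy_cohort <- function(n = 200, seed = 1, beta = 0.7, shape = 1.2,
                       scale = 10, cens = 18) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  t_ev <- scale * (-log(stats::runif(n)) / exp(x * beta))^(1 / shape)
  time <- pmin(t_ev, cens)
  data.frame(time = time, event = as.integer(t_ev <= cens), x = x)
}
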