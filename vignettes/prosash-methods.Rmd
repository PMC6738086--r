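---
title: "Methods behind prosash: the model, its fitting engine and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind prosash}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosash)
```

## The prediction problem

Median overall survival under sorafenib in advanced hepatocellular
carcinoma is around 9–10 months, but individual survival ranges from under
three months to beyond two years. The PROSASH model turns nine baseline
clinical features into an individual survival curve and a four-level risk
category. This package evaluates the published model exactly, re-implements
the class of models it was built with so the whole pipeline can be refitted
and validated, and ships a synthetic cohort generator so everything is
testable without the proprietary trial data.

## The model

The model is a proportional-hazards flexible parametric (Royston–Parmar)
survival model. On the log-cumulative-hazard scale,

$$\log H(t \mid x) = s(\log t) + \eta(x),$$

where $s$ is a restricted cubic spline in $\log t$ (natural logs, $t$ in
months) and $\eta$ is the linear predictor. The restricted basis is
$\{1, u, z_1(u), \dots, z_m(u)\}$ with
$z_j(u) = (u-k_j)_+^3 - \lambda_j (u-k_{\min})_+^3 -
(1-\lambda_j)(u-k_{\max})_+^3$ and
$\lambda_j = (k_{\max}-k_j)/(k_{\max}-k_{\min})$, which forces linearity in
$\log t$ beyond the boundary knots — extrapolation beyond the observed
follow-up is therefore log-linear by construction and no extra damping is
applied, though predictions past the follow-up horizon carry a flag.

The published baseline uses knots $(-1.017, 1.833, 3.443)$ on log-months
and $\gamma = (-8.167, 2.465, 0.113)$, giving
$S_0(t) = \exp(-\exp(s(\log t)))$ and
$S(t \mid x) = S_0(t)^{\exp(\eta(x))}$. The linear predictor combines
vascular invasion, age centred at 60 years (with an age-by-invasion
interaction applied only when invasion is present), ECOG 1 vs 0, natural
logs of AFP, creatinine and AST, albumin, extra-hepatic spread, and
aetiology with HCV as reference. All published constants live in one
versioned JSON asset (`inst/extdata/prosash_model.json`) that both the code
paths and the tests read; they are never inlined.

Risk categories cut $\eta$ at 2.898, 3.666 and 4.559 — the training-set
15th/50th/85th centiles — with closed upper bounds ($\eta \le$ cutoff),
matching the printed interval notation. $\eta$ is not rounded before
categorisation. Centiles are computed with the type-1 inverse-ECDF
quantile, which reproduces the exact 75/175/175/75 split of a 500-patient
training set.

Units are load-bearing: the printed spline reproduces the printed baseline
survival only with time in months and natural logs, and the covariate
coefficients assume ng/ml, g/l, µmol/L and U/L. The CSV reader therefore
treats implausible scales (times that look like days, creatinine that looks
like mg/dl, ages outside 18–100) as hard errors rather than warnings, and
non-positive AFP/creatinine/AST are rejected rather than clamped — a
detection-limit floor is a caller decision that must be explicit. Age is
used as a real number, not floored.

## Fitting

`flexpar()` maximises the right-censored log-likelihood

$$\ell = \sum_i d_i\left[\log s'(\log t_i) - \log t_i + s(\log t_i) +
x_i'\beta\right] - \sum_i \exp\!\big(s(\log t_i) + x_i'\beta\big)$$

with analytic gradient and Hessian. Design choices that matter:

* **Knots.** Boundary knots at the minimum and maximum *uncensored* log
  times; internal knots at equally spaced centiles of the uncensored log
  times (df = 2 puts one knot at the median). This convention reproduces
  the published knot interval, which matches the log of the observed
  survival range of the training arm.
* **Initialisation.** $\gamma$ is seeded by regressing
  $\log(-\log \hat S_{KM})$ on the spline basis at event times; $\beta$
  starts at zero. This derivative-free start is stable across the
  simulated cohorts.
* **Optimisation.** BFGS on the penalised likelihood, then Newton polishing
  with the analytic Hessian until the gradient infinity-norm is below
  1e-6. A negative fitted hazard at an event time (possible for extreme
  spline coefficients during the search) is handled softly: the likelihood
  returns a large negative penalised value with a retreat direction instead
  of raising an error, so no constrained optimiser is needed. Non-finite
  event terms cannot leak in from censored rows because the event sum is
  taken over event rows only.
* **Covariance.** Inverse negative analytic Hessian at the optimum,
  symmetrised.
* **Time-dependent effects.** A covariate's proportionality is tested by
  adding covariate-by-basis interaction terms (the non-constant basis
  functions) and likelihood-ratio testing against the proportional fit.
* **Model building.** Spline df is chosen by sequential LR tests over
  ascending candidates (smallest df not rejected against the next larger at
  5%, ties toward fewer knots). Backward selection drops, per round, the
  removable term with the largest LR p-value above 5%; factor levels and
  interactions drop as whole terms and main effects are protected while an
  interaction containing them remains, so the procedure is deterministic
  given column order. LR rather than Wald p-values are used throughout,
  consistent with the rest of the pipeline.

Martingale residuals $r_i = d_i - \hat H_i(t_i)$ support functional-form
checking. One subtlety: the maximum-likelihood score equation forces the
residuals to be orthogonal to every covariate *as modelled*, so regressing
residuals on the modelled covariate is vacuous. `functional_form_check()`
is therefore meant to be pointed at a *candidate alternative form* (for
instance, $\log z$ when $z$ entered linearly); a slope beyond two standard
errors flags the alternative as worth adopting.

The fit is invariant where it should be: rescaling time months→years
shifts $\gamma$ but leaves coefficients, hazard ratios and likelihood
*differences* unchanged, which the suite checks to 1e-6.

## Discrimination

Harrell's c-index uses the standard comparable-pair rules (pairs tied on
time are comparable only when exactly one member is an event; score ties
count one half) and is verified exactly against an exhaustive
pair-enumeration oracle.

The D statistic is computed as: rank the prognostic index, map ranks to
Blom rankits $\Phi^{-1}((r_i - 3/8)/(n + 1/4))$, scale by
$\kappa = \sqrt{8/\pi}$, and take the coefficient of this constructed
covariate in an auxiliary proportional-hazards fit on the same outcome.
The auxiliary fit uses the package's own spline engine (df = 2) rather
than a partial-likelihood fit, keeping a single likelihood code path;
on simulated data the two agree closely. Explained variation follows as
$R^2_D = (D^2/\kappa^2) / (\pi^2/6 + D^2/\kappa^2)$. With a normal
prognostic index of standard deviation $\sigma$ acting multiplicatively
on the hazard, $D \approx \kappa\sigma$, which the suite recovers within
10% at $n = 2000$.

Bootstrap intervals are percentile intervals over row resamples (200
replicates by default, mirroring the model's published validation),
unstratified, with a capped redraw of degenerate resamples.

## Calibration

Observed survival per risk category is Kaplan–Meier (via the survival
package) with log(−log)-scale Greenwood confidence limits and
Brookmeyer–Crowley median intervals; a median whose band never crosses 50%
is reported as `NA` (not reached). Predicted survival per category is the
**mean of the members' individual curves**, not the curve at the mean
linear predictor — the two genuinely differ: $\exp(-H_0 e^\eta)$ is convex
in $\eta$ only where $H_0 e^\eta > 1$ (survival below $1/e$) and concave
otherwise, so the mean curve sits below the curve-at-the-mean early in
follow-up and above it late. The suite checks both regimes. Group hazard
ratios come from a single-factor fit of the same spline engine (df = 2);
a category without events is reported with an infinite-interval flag
rather than an error.

## The synthetic cohort generator

The generator defines the study conditions every stochastic test runs
under. Covariates are drawn independently from the training arm's
marginals: age truncated-normal (60, 12.2) on 18–90 years; ECOG 1 with
probability 0.40; vascular invasion 0.29; extra-hepatic spread 0.72;
aetiology HCV/HBV/other 0.19/0.43/0.38; albumin normal (39, 5.2) g/l. AFP,
AST and creatinine are log-normal with the median matched exactly and the
spread solved from the interquartile *ratio* (matching all three quartiles
of a log-normal is overdetermined; median plus IQR width is preferred), so
AFP is centred at 181 ng/ml with quartiles spanning 8.5–2984.

Event times are drawn from the published model by inverse transform:
$u \sim U(0,1)$ and $t$ solves $S(t) = u$ by monotone root-finding on
$\log t$, with uniforms clamped away from 0 and 1 at machine precision.
Censoring composes an administrative cutoff at 31.3 months with
independent exponential dropout. The dropout rate default (0.013 per
month) was calibrated once, by simulation at $n = 20{,}000$, so that the
default configuration yields a death fraction of about 0.75, inside the
0.70–0.80 band the two trial arms bracket; it is fixed in
`cohort_config()` and not a tuning dial. Missingness injection is MCAR
with per-field defaults mirroring the training arm's missingness pattern
(including variables that were candidates but left the final model),
giving an expected complete-case yield of ~0.84; imputation itself is out
of scope — only injection and complete-case filtering are provided.

What the generator deliberately does **not** emulate: correlations between
covariates (only marginals are public, so independence is assumed, which
slightly inflates the spread of the linear predictor), informative
censoring, inter-trial differences (e.g. a minority of Child-Pugh B
patients whose status is only partly captured by albumin), and pre/post
study treatments. Passing calibration and recovery tests on generated
cohorts therefore demonstrates internal consistency of the machinery, not
real-world transportability, which needs external clinical validation.

## Numerical choices and degenerate inputs

* Quantiles: type-1 inverse ECDF for risk cutoffs; default type for knot
  centiles.
* Root-finding: `uniroot` at tolerance 1e-12 on a bracket widened until it
  straddles the target; valid because any fitted $s$ is increasing where
  the hazard is positive.
* Median survival: `NA` sentinel when $S$ at the horizon still exceeds
  0.5.
* Degenerate inputs: empty prediction input produces a header-only output
  with a warning; a cohort collapsing into one risk category reports the
  other rows as `NA`; constant prognostic indices give $D = 0$ with a
  warning; a constant covariate in the functional-form check is an error.

## Problem sizes used by the tests

The suite favours a few deep checks per operation: coefficient recovery
runs 25 cohorts of $n = 2000$; discrimination and calibration
self-consistency use cohorts of 500–1000 over several seeds; oracle
comparisons (concordance pairs, product-limit, Weibull likelihood) run on
exhaustive or small instances where exactness is asserted rather than
approximated. All stochastic tests carry explicit seeds.

## Known limitations

The engine fits only the log-cumulative-hazard scale (no odds or probit
link), without left truncation, interval censoring or cure fractions.
Backward selection is the classical stepwise procedure the model was built
with, inheriting its known instability at weak signals. The published
constants are treated as frozen; recalibration (intercept/slope updating)
is intentionally absent.
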