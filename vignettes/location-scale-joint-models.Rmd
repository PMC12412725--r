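---
title: "Location-scale joint models for a longitudinal marker and competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-scale joint models for a longitudinal marker and competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lsjoint` fits a shared-random-effect joint model for a repeatedly measured
marker (the motivating application scale is systolic blood pressure in mmHg)
and `K` competing time-to-event outcomes. Its distinguishing feature is that
the *within-subject residual variability* of the marker is itself
subject-specific and time-dependent, and may drive the event hazards.

The longitudinal submodel is a location-scale linear mixed model. For
subject `i` at time `t`,

    Y_i(t)   = X_i(t)' beta + Z_i(t)' b_i + eps_i(t),
    eps_i(t) ~ N(0, sigma_i(t)^2),
    log sigma_i(t) = O_i(t)' mu + M_i(t)' tau_i,

where `X` and `O` hold functions of time (with analytic derivatives) and
subject-level covariates, `Z` and `M` are their random-effect sub-designs
(always containing the intercept), and the stacked random effects
`u_i = (b_i, tau_i)` are multivariate normal with covariance `Sigma`,
parameterized through its Cholesky factor. The "location" part describes
the subject's trajectory; the "scale" part lets each subject carry their
own, possibly time-varying, residual SD — the model-based analogue of
visit-to-visit variability.

Each cause-specific hazard is proportional, loaded on three current
features of the trajectory:

    lambda_ik(t) = lambda0_k(t) exp( W_ik' gamma_k
                     + alpha1_k * y_i(t) + alpha2_k * y_i'(t)
                     + alphaS_k * sigma_i(t) ),

with `y_i(t)` the error-free marker value, `y_i'(t)` its slope and
`sigma_i(t)` the current residual SD. The baseline hazard `lambda0_k` can
be exponential, Weibull (`kappa t^(kappa-1) e^zeta0`, with `kappa`
estimated on the log scale so positivity is automatic) or a cubic B-spline
on the log hazard with `Q` interior knots placed at quantiles of the
observed event times (`Q + 4` coefficients; outside the boundary knots the
log baseline continues constantly, so predictions beyond the last event
time remain defined).

Censored subjects (`status = 0`) contribute only survival terms; subjects
with no marker rows contribute only their event information. Left
truncation (delayed entry) divides each subject's likelihood contribution
by the probability of being event-free at the entry time; it is off by
default because the shipped simulation designs have no truncation.

## Estimation

The marginal likelihood integrates the conditional longitudinal and
survival contributions over `(b_i, tau_i)`. The integral has no closed
form; it is approximated by quasi-Monte-Carlo: Sobol points (Joe-Kuo
direction numbers, dimensions up to 10) mapped through the standard-normal
quantile function and scaled by the Cholesky factor of `Sigma`. The same
draw set is shared by all subjects and all iterations, so the objective is
a fixed, smooth, deterministic function of the parameters during
optimization. The first Sobol point (the origin) is always skipped; an
optional seeded digital-shift scrambling is available. All per-subject
averages use log-sum-exp stabilization.

Cumulative hazards use the 15-point Gauss-Kronrod rule. Two node layouts
exist. Inside the likelihood the nodes sit directly on `[0, T_i]` and are
precomputed once per dataset, which keeps evaluations fast and the
objective smooth in the parameters. The exported `cumulative_hazard()`
defaults to a Weibull-adapted layout: the substitution `s = t^kappa`
absorbs the `t^(kappa-1)` factor, whose derivative singularity at zero
otherwise limits a 15-point rule to roughly 4-5 digits; after the
substitution the rule is exact when all association coefficients vanish.

Maximization uses a Marquardt-Levenberg ascent: Newton steps on a
diagonally inflated Hessian (`H_ii + phi((1-rho)|H_ii| + rho tr(H))`,
with `(phi, rho)` escalated from `(0.01, 0)` until the matrix is usable
and the step improves the objective, plus step-halving). Iteration stops
when parameter stability (`max |delta theta|^2 < 1e-4`), objective
stability (`|delta loglik| < 1e-4`) and the relative distance to the
maximum (`g' H^{-1} g / m < 1e-3`) all hold. Two implementation choices
speed up the climb without touching the converged answer:

* During the early climb the Hessian is approximated by the cross-product
  of per-subject score vectors (computed by central finite differences of
  the per-subject log-likelihood contributions). Near the optimum — when
  improvement stalls or the relative distance to the maximum drops below
  0.02 — the algorithm switches to true finite-difference Hessians, which
  drive the gradient to zero in a few iterations. Standard errors always
  come from a finite-difference Hessian.
* The baseline log-hazard level and the current-value/current-SD
  association coefficients are nearly collinear when the marker lives far
  from zero (a marker around 140 units makes `zeta0 + 140 alpha1` the
  identified combination). The optimizer therefore works in an exactly
  equivalent linear reparameterization in which each baseline intercept
  absorbs `center * alpha` (centers: mean marker value, zero slope, the
  initial residual-SD scale); estimates, gradients and Hessians are mapped
  back to the natural scale afterwards, with no approximation.

The finite-difference scheme uses per-coordinate steps
`max(1e-4, 1e-4 |theta_j|)`; Hessians use forward cross-differences with
central diagonals (`m(m+3)/2 + 1` evaluations) and a full central scheme
is available.

Estimation follows a two-step strategy. Step 1 climbs to convergence with
a modest number `S1` of Sobol draws. Step 2 restarts from the step-1
estimate with `S2 > S1` draws and iterates — at least once — until the
finite-difference Hessian is negative definite with condition number
below `1e12`; that Hessian provides the covariance of the estimates.
Covariance entries of `Sigma` and Weibull shapes are reported on their
natural scales with delta-method standard errors. If `S1 == S2` the
second step reduces to computing the Hessian at the step-1 optimum. When
the step-2 Hessian never becomes usable within its iteration budget the
step-1 estimates are returned with a warning.

Initial values come from a preliminary location-scale mixed model (no
event terms; itself started from an `lme4` fit with a homogeneous
residual) and cause-specific parametric survival fits with all association
coefficients at zero. A near-zero random-effect variance estimate
(below `2e-3`) triggers a warning, because associations loading on that
effect would be unidentifiable.

The number of QMC draws matters more when subjects carry many
measurements: with dense follow-up the conditional posterior of the random
effects is sharp and too few deterministic draws inflate the random-effect
variance estimates. With the 7- and 13-visit designs shipped here,
`S1 = 250` to `500` is adequate for point estimates; standard errors use
`S2` of `1000` to `5000`.

## Predictions

`empirical_bayes_modes()` maximizes each subject's conditional posterior
`f(Y_i | u) f(T_i, delta_i | u) f(u)` over the random effects with the
same Marquardt-Levenberg routine (falling back to the prior mean with a
warning if the maximization fails). `marker_prediction_band()` returns the
trajectory at the modes with the pointwise band `+/- 1.96 sigma_i(t)` — on
the SD scale, so heterogeneous subjects get their own band widths.

`predict_risk()` computes the probability of a cause-`k` event in
`(s, s + t]` for a subject event-free at the landmark `s`, given the
marker history strictly before `s`: a ratio of QMC averages in which each
random-effect draw is weighted by its history likelihood, the inner
cumulative hazards use the Gauss-Kronrod rule on `[0, u]` for each outer
node `u`, and the outer time integral uses the same rule on `[s, s + t]`.
The result is a probability by construction; `t <= 0` returns 0. The 95%
confidence band draws `L` parameter vectors from
`N(theta_hat, vcov)` — valid draws by construction on the working scale,
since `Sigma` is parameterized by its Cholesky factor and Weibull shapes
by logs; any draw that still fails to produce a finite probability is
redrawn and counted — and reports the 2.5th and 97.5th percentiles of the
recomputed predictions.

## The simulator

`simulate_lsjm()` generates the shipped study designs. Visits are anchor
schedules (7 anchors: 0, 0.5, then yearly to 5 years; or 13 anchors:
quarterly in year 1, then twice yearly) jittered uniformly by one month,
clipped at zero. Marker values follow
`Y = 142 + b0 + (3 + b1) t + eps` with
`log sigma = 2.4 + tau0 + (0.05 + tau1) t`. Event times for each cause are
drawn by inverse-transform sampling: `U ~ Uniform(0,1)` and Brent
root-finding of `Lambda_k(t) + log U = 0`, with the cumulative hazard
computed by adaptive quadrature along the subject's latent trajectory and
the bracket expanded geometrically up to 100 years (the hazard exponent is
capped at 500 to keep the integrand finite far outside the design range).
Censoring is the subject's last scheduled visit; the observed time is the
minimum of the latent event times and censoring, and marker rows after it
are removed.

Scenario presets A-D reproduce the printed generating covariances (A/B:
mean and variance effects independent; C/D: fully correlated) and the
two Weibull cause-specific hazards with associations
`(0.02, 0.01, 0.07)` and `(-0.01, -0.14, 0.15)` on value, slope and SD.
Two details deserve a note. The generating text prints Weibull shapes
1.12/1.32 in one place and true values 1.1/1.3 in the results tables; the
presets use 1.1/1.3, consistent with the tables' bias columns. Scenario E
(quadratic generating mean, fit linear) and F (constant generating
variance, fit time-varying) are robustness presets whose exact generating
values are free parameters; the defaults keep scenario A's survival side
with a single cause, scenario F setting `Var(tau0) = 0.13` (an
application-scale value) with no variance slope.

What the simulator does *not* emulate: informative visit processes,
missed visits, covariate measurement error, interval censoring, or
non-Gaussian measurement noise. Passing the recovery tests therefore
demonstrates internal statistical correctness of estimator and simulator
under the stated generating model, not robustness to those features of
real cohort data.

## Numerical choices and edge cases

* Quadrature: single 15-point Gauss-Kronrod panels; likelihood nodes are
  parameter-independent; the exported cumulative hazard adapts Weibull
  nodes (see above).
* QMC: Sobol with origin skipped; optional digital-shift scrambling. All
  randomness in a fit flows from explicit seeds; refits are bit-identical.
* Complete underflow of a subject's QMC average returns a large negative
  contribution (-1e10) with a warning rather than `NaN`.
* Ties in simulated visit schedules (possible after clipping at zero) are
  separated by a tiny deterministic offset; tied event times in the
  Nelson-Aalen estimator are aggregated.
* Degenerate inputs: subjects with zero marker rows are kept
  (survival-only); an entry time after the observed time is an error;
  event status outside `0..K` is an error with the offending rows named.
* The empirical-Bayes fallback (prior mean) and the step-2 fallback
  (step-1 Hessian) both warn rather than fail.

## Validation sizes

The package's statistical validation (the acceptance test file and
`scripts/acceptance.R`) runs scaled-down replication studies chosen to
exercise the full pipeline on a single CPU: scenario A recovery with
N = 200 subjects and 6 replications at `S1 = 250 / S2 = 1000`; prediction
calibration on one scenario-B dataset of 150 subjects with `L = 1000`
Monte-Carlo parameter draws; the scenario-F robustness check with 20
replications of 80 subjects. All comparisons use tolerances that adapt to
the replication count (Monte-Carlo standard errors, exact binomial
coverage bands), so reducing the study size widens only the Monte-Carlo
bands, never the nominal criteria. One caveat is intrinsic to small
replication counts: the empirical SD of a handful of estimates is itself
noisy, so the ratio of model-based to empirical standard errors is a
rough diagnostic at this size. The boundary parameter `Var(tau0)` (generating
value `1e-4`) is estimated with the upward bias expected near a boundary;
its Wald interval under-covers accordingly, which the exact binomial band
accommodates at small replication counts.

## Known limitations

* Hazard associations are Markovian in the current features; lagged
  dependence is not implemented.
* Measurement errors are Gaussian; no robust/heavy-tailed option.
* The cross-validated discrimination (AUC) workflow and informative-visit
  extensions are out of scope.
* B-spline baselines extrapolate as constants beyond the boundary knots;
  this is deliberate but crude for long-horizon predictions.
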