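# Deterministic model quantities: marker mean and slope, residual SD,
# cause-specific hazards, Gauss-Kronrod cumulative hazards, baseline
# hazard variants.

# 15-point Gauss-Kronrod rule on [-1, 1]
gk15_nodes <- c(
  -0.991455371120813, -0.949107912342759, -0.864864423359769,
  -0.741531185599394, -0.586087235467691, -0.405845151377397,
  -0.207784955007898, 0,
  0.207784955007898, 0.405845151377397, 0.586087235467691,
  0.741531185599394, 0.864864423359769, 0.949107912342759,
  0.991455371120813)
gk15_weights <- c(
  0.022935322010529, 0.063092092629979, 0.104790010322250,
  0.140653259715525, 0.169004726639267, 0.190350578064785,
  0.204432940075298, 0.209482141084728, 0.204432940075298,
  0.190350578064785, 0.169004726639267, 0.140653259715525,
  0.104790010322250, 0.063092092629979, 0.022935322010529)

# nodes and scaled weights for \int_{a}^{b}
gk15_panel <- function(a, b) {
  h <- (b - a) / 2
  list(t = (a + b) / 2 + h * gk15_nodes, w = h * gk15_weights)
}

#' Current marker mean, slope and residual SD
#'
#' Deterministic trajectory quantities of the location-scale mixed model at
#' time `t` for a subject with random effects `b` (mean) and `tau` (log-SD):
#' `marker_mean()` returns `X(t)'beta + Z(t)'b`, `marker_slope()` its
#' analytic time-derivative, and `residual_sd()` returns
#' `exp(O(t)'mu + M(t)'tau)`, which is positive by construction.
#'
#' @param design An [ls_design()].
#' @param t Time(s), in the time unit of the data (years in the shipped
#'   scenarios).
#' @param beta,mu Fixed-effect vectors of the mean and log-SD models.
#' @param b,tau Random-effect vectors (`length(design$random_mean)` and
#'   `length(design$random_variance)`).
#' @param covariates Named list/row of subject-level covariates, if the
#'   design uses any.
#' @return Numeric vector along `t`.
#' @export
marker_mean <- function(design, t, beta, b = NULL, covariates = NULL) {
  if (is.null(b)) b <- numeric(length(design$random_mean))
  X <- mean_design(design, t, covariates)
  check_len(beta, ncol(X), "beta")
  check_len(b, length(design$random_mean), "b")
  drop(X %*% beta) + drop(X[, design$random_mean, drop = FALSE] %*% b)
}

#' @rdname marker_mean
#' @export
marker_slope <- function(design, t, beta, b = NULL, covariates = NULL) {
  if (is.null(b)) b <- numeric(length(design$random_mean))
  dX <- mean_design(design, t, covariates, deriv = TRUE)
  check_len(beta, ncol(dX), "beta")
  check_len(b, length(design$random_mean), "b")
  drop(dX %*% beta) + drop(dX[, design$random_mean, drop = FALSE] %*% b)
}

#' @rdname marker_mean
#' @export
residual_sd <- function(design, t, mu, tau = NULL, covariates = NULL) {
  if (is.null(tau)) tau <- numeric(length(design$random_variance))
  O <- variance_design(design, t, covariates)
  check_len(mu, ncol(O), "mu")
  check_len(tau, length(design$random_variance), "tau")
  exp(drop(O %*% mu) + drop(O[, design$random_variance, drop = FALSE] %*% tau))
}

check_len <- function(x, n, what) {
  if (length(x) != n) {
    stop(what, " has length ", length(x), ", expected ", n, call. = FALSE)
  }
  invisible(x)
}

#' Baseline hazard specification and evaluation
#'
#' Three parametric families for the cause-specific baseline hazard:
#' exponential (`lambda0(t) = exp(zeta0)`), Weibull
#' (`lambda0(t) = kappa t^(kappa - 1) exp(zeta0)`) and cubic B-splines on
#' the log hazard (`lambda0(t) = exp(sum eta_q B_q(t))`, with `Q` interior
#' knots and `Q + 4` coefficients). Outside the B-spline boundary knots the
#' log baseline is continued constantly at the boundary value.
#'
#' @param variant `"exponential"`, `"weibull"` or `"bsplines"`.
#' @param pars Named parameters: `zeta0`; `kappa` and `zeta0`; or the
#'   spline coefficients `eta`.
#' @param knots Interior knot vector (B-splines only).
#' @param boundary Length-2 boundary knots (B-splines only).
#' @return `baseline_hazard_spec()` returns a `baseline_hazard` object;
#'   `baseline_hazard()` evaluates it, a positive vector along `t`.
#' @export
baseline_hazard_spec <- function(variant = c("weibull", "exponential", "bsplines"),
                                 pars, knots = NULL, boundary = NULL) {
  variant <- match.arg(variant)
  if (variant == "bsplines") {
    if (is.null(boundary) || length(boundary) != 2) {
      stop("bsplines baseline needs 2 boundary knots", call. = FALSE)
    }
    if (length(pars) != length(knots) + 4) {
      stop("bsplines baseline needs Q + 4 coefficients for Q interior knots",
           call. = FALSE)
    }
  }
  if (variant == "weibull" && pars[["kappa"]] <= 0) {
    stop("Weibull shape kappa must be positive", call. = FALSE)
  }
  structure(list(variant = variant, pars = pars, knots = knots,
                 boundary = boundary),
            class = "baseline_hazard")
}

#' @param bh A `baseline_hazard` object.
#' @param t Evaluation time(s); positive for the Weibull with
#'   `kappa != 1`.
#' @rdname baseline_hazard_spec
#' @export
baseline_hazard <- function(bh, t) {
  stopifnot(inherits(bh, "baseline_hazard"))
  switch(bh$variant,
    exponential = rep(exp(bh$pars[["zeta0"]]), length(t)),
    weibull = {
      k <- bh$pars[["kappa"]]
      if (any(t < 0)) stop("Weibull baseline needs t >= 0", call. = FALSE)
      k * t^(k - 1) * exp(bh$pars[["zeta0"]])
    },
    bsplines = exp(drop(bspline_log_basis(bh, t) %*% bh$pars)))
}

# Cubic B-spline basis rows at times t, with constant continuation of the
# log baseline outside the boundary knots.
bspline_log_basis <- function(bh, t) {
  lo <- bh$boundary[1]; hi <- bh$boundary[2]
  out_of_span <- t < lo | t > hi
  if (any(out_of_span)) {
    message("baseline B-spline evaluated outside [", signif(lo, 4), ", ",
            signif(hi, 4), "]; log-hazard continued constantly at the boundary")
  }
  tc <- pmin(pmax(t, lo), hi)
  kn <- c(rep(lo, 4), bh$knots, rep(hi, 4))
  splines::splineDesign(kn, tc, ord = 4)
}

# quantile-based interior knots from observed event times
default_spline_knots <- function(event_times, n_knots = 3) {
  stats::quantile(event_times, probs = seq_len(n_knots) / (n_knots + 1),
                  names = FALSE, type = 7)
}

#' Cause-specific hazard of the joint model
#'
#' `hazard()` evaluates
#' `lambda_k(t) = lambda0_k(t) exp(W'gamma + a1 y(t) + a2 y'(t) + as sigma(t))`
#' at given random effects; `cumulative_hazard()` integrates it over
#' `[t0, t1]` with a single 15-point Gauss-Kronrod panel (the rule used
#' throughout the likelihood).
#'
#' @param design An [ls_design()].
#' @param t,t0,t1 Times; `0 <= t0 <= t1`.
#' @param params Structured parameters (see [params_unflatten()]).
#' @param b,tau Random-effect vectors.
#' @param cause Cause index `k`.
#' @param baselines List of `baseline_hazard` objects, one per cause.
#' @param covariates Named subject-level covariates (survival covariates
#'   are looked up by the design's `surv_covariates` names).
#' @return Positive hazard values / a nonnegative cumulative hazard.
#' @export
hazard <- function(design, t, params, b, tau, cause, baselines,
                   covariates = NULL) {
  lp <- hazard_linear_predictor(design, t, params, b, tau, cause, covariates)
  baseline_hazard(baselines[[cause]], t) * exp(lp)
}

# covariate + association exponent of the cause-specific hazard (without
# the baseline factor)
hazard_linear_predictor <- function(design, t, params, b, tau, cause,
                                    covariates = NULL) {
  ck <- params$causes[[cause]]
  lp <- rep(0, length(t))
  wn <- if (length(design$surv_covariates) >= cause) {
    design$surv_covariates[[cause]]
  } else character()
  if (length(wn)) {
    w <- unlist(covariates)[wn]
    lp <- lp + sum(w * ck$gamma)
  }
  a <- ck$alpha
  if (a[["value"]] != 0) {
    lp <- lp + a[["value"]] * marker_mean(design, t, params$beta, b, covariates)
  }
  if (a[["slope"]] != 0) {
    lp <- lp + a[["slope"]] * marker_slope(design, t, params$beta, b, covariates)
  }
  if (a[["sigma"]] != 0) {
    lp <- lp + a[["sigma"]] * residual_sd(design, t, params$mu, tau, covariates)
  }
  lp
}

#' @param nodes Node placement for the 15-point rule. `"adapted"`
#'   (default) absorbs a Weibull baseline's `t^(kappa - 1)` factor by the
#'   exact substitution `s = t^kappa` before placing the nodes, removing
#'   the endpoint derivative singularity (the rule is then exact when all
#'   association coefficients are zero). `"fixed"` places the nodes
#'   directly on `[t0, t1]`, mirroring the likelihood's precomputed-node
#'   quadrature.
#' @rdname hazard
#' @export
cumulative_hazard <- function(design, t0, t1, params, b, tau, cause,
                              baselines, covariates = NULL,
                              nodes = c("adapted", "fixed")) {
  nodes <- match.arg(nodes)
  if (t1 < t0) stop("cumulative_hazard needs t0 <= t1", call. = FALSE)
  if (t1 == t0) return(0)
  bh <- baselines[[cause]]
  if (nodes == "adapted" && bh$variant == "weibull") {
    kap <- bh$pars[["kappa"]]
    gk <- gk15_panel(t0^kap, t1^kap)
    tq <- gk$t^(1 / kap)
    # the baseline factor kappa t^(kappa-1) e^zeta0 integrates exactly in
    # s = t^kappa; only exp(linear predictor) is left to the quadrature
    lp <- hazard_linear_predictor(design, tq, params, b, tau, cause,
                                  covariates)
    return(exp(bh$pars[["zeta0"]]) * sum(gk$w * exp(lp)))
  }
  gk <- gk15_panel(t0, t1)
  sum(gk$w * hazard(design, gk$t, params, b, tau, cause, baselines, covariates))
}
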