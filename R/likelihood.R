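# Marginal log-likelihood of the joint model. The exported per-subject
# operations are a plain R reference implementation; `total_loglik()` can
# route through them (`engine = "r"`) or through the compiled fast path
# (`engine = "cpp"`, the default). The two are tested against each other.

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

#' Conditional log-likelihood contributions given the random effects
#'
#' `loglik_longitudinal_given_re()` is the Gaussian measurement
#' log-density `sum_j log N(Y_ij; y_i(t_ij), sigma_i(t_ij)^2)`;
#' `loglik_event_given_re()` is the competing-risk term
#' `-sum_k Lambda_ik(T_i) + 1(delta_i = k) log lambda_ik(T_i)` (censored
#' subjects keep only the survival part).
#'
#' @param subject A subject record: list with `visit_times`,
#'   `marker_values`, `time`, `status`, `entry`, `covariates` (see
#'   [prepare_data()]).
#' @param design An [ls_design()].
#' @param params Structured parameters ([params_unflatten()]).
#' @param b,tau Random-effect values.
#' @param baselines Per-cause `baseline_hazard` objects.
#' @return A scalar log-likelihood contribution.
#' @export
loglik_longitudinal_given_re <- function(subject, design, params, b, tau) {
  n <- length(subject$visit_times)
  if (n == 0) return(0)
  m <- marker_mean(design, subject$visit_times, params$beta, b,
                   subject$covariates)
  s <- residual_sd(design, subject$visit_times, params$mu, tau,
                   subject$covariates)
  sum(stats::dnorm(subject$marker_values, mean = m, sd = s, log = TRUE))
}

#' @rdname loglik_longitudinal_given_re
#' @export
loglik_event_given_re <- function(subject, design, params, b, tau, baselines) {
  stopifnot(subject$time > 0)
  K <- length(baselines)
  ll <- 0
  for (k in seq_len(K)) {
    ll <- ll - cumulative_hazard(design, 0, subject$time, params, b, tau, k,
                                 baselines, subject$covariates)
  }
  if (subject$status > 0) {
    ll <- ll + log(hazard(design, subject$time, params, b, tau,
                          subject$status, baselines, subject$covariates))
  }
  ll
}

#' Quasi-Monte-Carlo marginal log-likelihood of one subject
#'
#' Approximates `log integral f(Y_i | b, tau) f(T_i, delta_i | b, tau)
#' f(b, tau) db dtau` by averaging the conditional likelihood over Sobol
#' draws of the random effects, with log-sum-exp stabilization. With
#' `delayed_entry`, the log probability of being event-free at the entry
#' time ([delayed_entry_correction()]) is subtracted.
#'
#' @inheritParams loglik_longitudinal_given_re
#' @param cfg A [qmc_config()].
#' @param delayed_entry Apply the left-truncation correction.
#' @return Scalar log-likelihood; never `NaN` (complete underflow returns a
#'   large negative value with a warning).
#' @export
marginal_loglik_subject <- function(subject, design, params, baselines, cfg,
                                    delayed_entry = FALSE) {
  U <- qmc_normal_draws(cfg, ncol(params$L), params$L)
  nb <- length(design$random_mean)
  ll <- vapply(seq_len(nrow(U)), function(s) {
    b <- U[s, seq_len(nb)]
    tau <- U[s, nb + seq_len(ncol(U) - nb)]
    loglik_longitudinal_given_re(subject, design, params, b, tau) +
      loglik_event_given_re(subject, design, params, b, tau, baselines)
  }, 0)
  out <- log_sum_exp(ll) - log(length(ll))
  if (!is.finite(out)) {
    warning("all QMC draws underflowed for subject ", subject$id)
    out <- -1e10
  }
  if (delayed_entry && subject$entry > 0) {
    out <- out - delayed_entry_correction(subject, design, params, baselines, cfg)
  }
  out
}

#' Delayed-entry (left-truncation) correction
#'
#' Log of the marginal probability of being free of all events at the
#' subject's entry time, `log integral exp(-sum_k Lambda_ik(T0i)) f(b, tau)`,
#' computed with the same QMC draws. Always `<= 0`; exactly 0 when the
#' entry time is 0.
#'
#' @inheritParams marginal_loglik_subject
#' @return Scalar log-probability.
#' @export
delayed_entry_correction <- function(subject, design, params, baselines, cfg) {
  if (subject$entry > subject$time) {
    stop("entry time exceeds observed time for subject ", subject$id,
         call. = FALSE)
  }
  if (subject$entry <= 0) return(0)
  U <- qmc_normal_draws(cfg, ncol(params$L), params$L)
  nb <- length(design$random_mean)
  ll <- vapply(seq_len(nrow(U)), function(s) {
    b <- U[s, seq_len(nb)]
    tau <- U[s, nb + seq_len(ncol(U) - nb)]
    -sum(vapply(seq_along(baselines), function(k) {
      cumulative_hazard(design, 0, subject$entry, params, b, tau, k,
                        baselines, subject$covariates)
    }, 0))
  }, 0)
  min(log_sum_exp(ll) - log(length(ll)), 0)
}

#' Total marginal log-likelihood
#'
#' Sum of per-subject QMC marginal log-likelihood contributions, minus the
#' delayed-entry corrections when the data were prepared with
#' `delayed_entry = TRUE`.
#'
#' @param data An [prepare_data()] object.
#' @param theta Flat parameter vector (see [param_map()]), or a structured
#'   parameter list.
#' @param cfg A [qmc_config()].
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation).
#' @param by_subject Return the vector of per-subject contributions
#'   instead of their sum.
#' @return Scalar log-likelihood (or an N-vector).
#' @export
total_loglik <- function(data, theta, cfg = qmc_config(),
                         engine = c("cpp", "r"), by_subject = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(data, "lsjm_data"))
  map <- data$model$map
  params <- if (is.numeric(theta)) params_unflatten(theta, map) else theta
  if (engine == "cpp") {
    E <- cached_std_draws(cfg, map$r)
    ll <- loglik_subjects_cpp(par_for_cpp(params, map), data$bundle, E,
                              data$delayed_entry)
  } else {
    baselines <- baselines_from_params(data, params)
    ll <- vapply(data$subjects, marginal_loglik_subject, 0,
                 design = data$model$design, params = params,
                 baselines = baselines, cfg = cfg,
                 delayed_entry = data$delayed_entry)
  }
  bad <- !is.finite(ll)
  if (any(bad)) {
    stop("non-finite log-likelihood contribution for subject(s) ",
         paste(utils::head(data$ids[bad], 5), collapse = ", "), call. = FALSE)
  }
  if (by_subject) ll else sum(ll)
}

# repackage structured parameters for the C++ kernel
par_for_cpp <- function(params, map) {
  causes <- lapply(seq_len(map$K), function(k) {
    ck <- params$causes[[k]]
    list(gamma = as.numeric(ck$gamma),
         a1 = ck$alpha[["value"]], a2 = ck$alpha[["slope"]],
         as = ck$alpha[["sigma"]],
         variant = switch(ck$baseline$variant,
                          exponential = 0L, weibull = 1L, bsplines = 2L),
         blpars = as.numeric(ck$baseline$pars))
  })
  list(beta = params$beta, mu = params$mu, L = params$L, causes = causes)
}
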