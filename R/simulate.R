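# Synthetic-data generator: location-scale trajectories with heterogeneous
# within-subject variance, competing event times drawn by inverting the
# cause-specific cumulative hazards with Brent root-finding, and censoring
# at the last scheduled visit.

#' Simulation scenario configurations
#'
#' Named presets for the shipped study designs. All use the blood-pressure
#' scale generating model `Y(t) = 142 + b0 + (3 + b1) t + eps(t)` with
#' `log sigma(t) = 2.4 + tau0 + (0.05 + tau1) t`, Weibull cause-specific
#' baselines and hazards loaded on the current value, current slope and
#' current residual SD:
#' \describe{
#'   \item{A}{7 visit anchors (0, 0.5, then yearly to 5 years), mean and
#'     variance random effects independent, two competing causes.}
#'   \item{B}{13 anchors (quarterly in year 1, then twice yearly to 5
#'     years), independent blocks, two causes.}
#'   \item{C}{visits as A, fully correlated 4 x 4 random-effect
#'     covariance.}
#'   \item{D}{visits as B, correlated covariance.}
#'   \item{E}{quadratic time trend in the generating mean (robustness
#'     preset; single cause).}
#'   \item{F}{constant generating residual SD, no variance slope
#'     (robustness preset; single cause).}
#' }
#' Visit anchors are jittered uniformly by +/- 1 month (1/12 year).
#'
#' @param scenario Preset letter.
#' @param n Number of subjects.
#' @param ... Overrides for preset fields (`beta`, `mu`, `Sigma`, `causes`,
#'   `anchors`, `jitter`, `t_max`).
#' @return A list of class `scenario_config` with the generating truth.
#' @export
scenario_config <- function(scenario = c("A", "B", "C", "D", "E", "F"),
                            n = 500, ...) {
  scenario <- match.arg(scenario)
  sigma_indep <- rbind(
    c(207.36, -17.4, 0, 0),
    c(-17.4, 9.28, 0, 0),
    c(0, 0, 0.0001, -0.0006),
    c(0, 0, -0.0006, 0.0157))
  sigma_corr <- rbind(
    c(210.25, -15.95, 2.9, -0.145),
    c(-15.95, 9.05, -0.304, 0.067),
    c(2.9, -0.304, 0.1309, -0.0206),
    c(-0.145, 0.067, -0.0206, 0.0141))
  anchors_a <- c(0, 0.5, 1, 2, 3, 4, 5)
  anchors_b <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5)
  cause1 <- list(kappa = 1.1, zeta0 = -7,
                 alpha = c(value = 0.02, slope = 0.01, sigma = 0.07))
  cause2 <- list(kappa = 1.3, zeta0 = -4,
                 alpha = c(value = -0.01, slope = -0.14, sigma = 0.15))
  base <- list(
    scenario = scenario, n = n,
    beta = c(142, 3), mu = c(2.4, 0.05),
    Sigma = sigma_indep,
    causes = list(cause1, cause2),
    anchors = anchors_a, jitter = 1 / 12, t_max = 100,
    design = ls_design(),
    re_structure = "independent")
  assign_fields <- function(cfg, fields) {
    for (nm in names(fields)) cfg[[nm]] <- fields[[nm]]
    cfg
  }
  cfg <- switch(scenario,
    A = base,
    B = assign_fields(base, list(anchors = anchors_b)),
    C = assign_fields(base, list(Sigma = sigma_corr,
                                 re_structure = "full")),
    D = assign_fields(base, list(Sigma = sigma_corr,
                                 anchors = anchors_b,
                                 re_structure = "full")),
    E = assign_fields(base, list(
      beta = c(142, 3, -0.3),
      causes = list(cause1),
      design = ls_design(mean_basis = time_poly(2), random_mean = c(1, 2)))),
    F = assign_fields(base, list(
      mu = 2.4,
      Sigma = rbind(c(207.36, -17.4, 0),
                    c(-17.4, 9.28, 0),
                    c(0, 0, 0.13)),
      causes = list(cause1),
      design = ls_design(variance_basis = time_poly(0)))))
  cfg <- assign_fields(cfg, list(...))
  ev <- eigen(cfg$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("Sigma is not positive semi-definite",
                             call. = FALSE)
  if (is.unsorted(cfg$anchors, strictly = TRUE)) {
    stop("visit anchors must be strictly increasing", call. = FALSE)
  }
  structure(cfg, class = "scenario_config")
}

# structured truth parameters of a scenario, on the model's own scale
truth_params <- function(cfg) {
  nb <- length(cfg$design$random_mean)
  L <- t(chol_psd(cfg$Sigma))
  causes <- lapply(cfg$causes, function(ck) {
    list(gamma = numeric(0),
         alpha = ck$alpha,
         baseline = list(variant = "weibull",
                         pars = c(kappa = ck$kappa, zeta0 = ck$zeta0)))
  })
  list(beta = cfg$beta, mu = cfg$mu, L = L, causes = causes)
}

# Cholesky-like lower factor for a PSD (possibly singular) matrix
chol_psd <- function(S) {
  r <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(r)) return(r)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  # return an upper factor shape consistent with chol(): t(L) with L lower
  qr.R(qr(t(e$vectors %*% diag(sqrt(v), nrow = length(v)))))
}

#' The model specification matching a scenario's generating truth
#'
#' @param cfg A [scenario_config()].
#' @return An [lsjm_model()] whose parameter map matches the truth, so that
#'   `params_flatten(truth, model$map)` is the generating parameter vector.
#' @export
scenario_model <- function(cfg) {
  lsjm_model(cfg$design, K = length(cfg$causes), baseline = "weibull",
             associations = list(c("value", "slope", "sigma")),
             re_structure = cfg$re_structure)
}

#' Jittered visit schedules
#'
#' Each anchor time is perturbed by `Uniform(-jitter, +jitter)`, clipped at
#' zero, sorted; exact duplicates are separated by a tiny deterministic
#' offset.
#'
#' @param cfg A [scenario_config()].
#' @return Numeric vector of visit times for one subject.
#' @export
generate_visits <- function(cfg) {
  v <- cfg$anchors + stats::runif(length(cfg$anchors), -cfg$jitter, cfg$jitter)
  v <- sort(pmax(v, 0))
  while (any(diff(v) <= 0)) {
    v[c(FALSE, diff(v) <= 0)] <- v[c(FALSE, diff(v) <= 0)] + 1e-8
    v <- sort(v)
  }
  v
}

#' Marker trajectory for one subject (pre-censoring)
#'
#' Draws `(b, tau) ~ N(0, Sigma)` and measurement noise with the
#' subject-specific time-dependent SD.
#'
#' @param cfg A [scenario_config()].
#' @param visits Visit times.
#' @param u Optional random-effect vector (drawn if missing).
#' @return List with `u`, `visits`, `values`.
#' @export
generate_subject_data <- function(cfg, visits = generate_visits(cfg), u = NULL) {
  nb <- length(cfg$design$random_mean)
  ntau <- length(cfg$design$random_variance)
  if (is.null(u)) {
    u <- drop(MASS::mvrnorm(1, mu = rep(0, nb + ntau), Sigma = cfg$Sigma))
  }
  b <- u[seq_len(nb)]; tau <- u[nb + seq_len(ntau)]
  m <- marker_mean(cfg$design, visits, cfg$beta, b)
  s <- residual_sd(cfg$design, visits, cfg$mu, tau)
  list(u = u, visits = visits, values = m + stats::rnorm(length(visits), 0, s))
}

#' Event time by inverse-transform sampling with Brent root-finding
#'
#' Draws `U ~ Uniform(0, 1)` (or uses a supplied value) and solves
#' `Lambda_k(t) + log U = 0` on `(0, t_max]` with Brent's method; the
#' cumulative hazard is computed by adaptive quadrature of the
#' cause-specific hazard along the subject's latent trajectory. Returns
#' `Inf` when no root exists below `t_max`.
#'
#' @param cfg A [scenario_config()].
#' @param u Random-effect vector of the subject.
#' @param cause Cause index.
#' @param unif Optional uniform draw.
#' @param tol Brent tolerance.
#' @return Event time (possibly `Inf`).
#' @export
generate_event_time <- function(cfg, u, cause, unif = stats::runif(1),
                                tol = 1e-10) {
  nb <- length(cfg$design$random_mean)
  b <- u[seq_len(nb)]; tau <- u[-seq_len(nb)]
  ck <- cfg$causes[[cause]]
  haz <- function(t) {
    lp <- ck$zeta0 +
      ck$alpha[["value"]] * marker_mean(cfg$design, t, cfg$beta, b) +
      ck$alpha[["slope"]] * marker_slope(cfg$design, t, cfg$beta, b) +
      ck$alpha[["sigma"]] * residual_sd(cfg$design, t, cfg$mu, tau)
    ck$kappa * t^(ck$kappa - 1) * exp(pmin(lp, 500))
  }
  cumhaz <- function(t) {
    stats::integrate(haz, 0, t, rel.tol = 1e-11, abs.tol = 1e-13,
                     subdivisions = 500L)$value
  }
  target <- -log(unif)
  # bracket the root, expanding geometrically up to the hard cap t_max
  upper <- max(cfg$anchors)
  ch <- cumhaz(upper)
  while (ch < target && upper < cfg$t_max) {
    upper <- min(2 * upper, cfg$t_max)
    ch <- cumhaz(upper)
  }
  if (ch < target) return(Inf)
  stats::uniroot(function(t) cumhaz(t) - target,
                 lower = 1e-12, upper = upper,
                 tol = tol, maxiter = 2000L)$root
}

#' Simulate a full competing-risk location-scale dataset
#'
#' Per subject: jittered visits, random effects, noisy marker values, one
#' latent event time per cause, censoring at the last scheduled visit
#' (`C_i`), `T_i = min(T*_1, ..., T*_K, C_i)`, and removal of marker
#' measurements after `T_i`.
#'
#' @param scenario Preset letter, or ignored when `config` is given.
#' @param n Number of subjects.
#' @param seed RNG seed; the dataset is reproducible given `(config, seed)`.
#' @param config Optional [scenario_config()] overriding `scenario`/`n`.
#' @return A list of class `lsjm_sim`: `marker` and `events` tibbles,
#'   the matrix `re` of true random effects, the `config`, and `truth`
#'   (structured generating parameters).
#' @export
simulate_lsjm <- function(scenario = "A", n = 500, seed = 1, config = NULL) {
  cfg <- if (is.null(config)) scenario_config(scenario, n = n) else config
  set.seed(seed)
  K <- length(cfg$causes)
  marker <- vector("list", cfg$n)
  events <- vector("list", cfg$n)
  re <- matrix(0, cfg$n, nrow(cfg$Sigma))
  for (i in seq_len(cfg$n)) {
    sd_ <- generate_subject_data(cfg)
    re[i, ] <- sd_$u
    cens <- max(sd_$visits)
    tk <- vapply(seq_len(K), function(k) generate_event_time(cfg, sd_$u, k), 0)
    tobs <- min(c(tk, cens))
    status <- if (min(tk) <= cens) which.min(tk) else 0L
    keep <- sd_$visits <= tobs
    marker[[i]] <- tibble::tibble(id = i, time = sd_$visits[keep],
                                  value = sd_$values[keep])
    events[[i]] <- tibble::tibble(id = i, entry = 0, time = tobs,
                                  status = status)
  }
  structure(
    list(marker = dplyr::bind_rows(marker), events = dplyr::bind_rows(events),
         re = re, config = cfg, truth = truth_params(cfg)),
    class = "lsjm_sim")
}

#' @export
print.lsjm_sim <- function(x, ...) {
  cat("<lsjm_sim> scenario", x$config$scenario, "with", x$config$n,
      "subjects\n")
  print(table(status = x$events$status))
  invisible(x)
}
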