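# Model fitting: preliminary location-scale mixed model, cause-specific
# parametric survival initialization, and the two-step quasi-Monte-Carlo
# maximum-likelihood fit of the joint model.

#' Fitting settings for the joint model
#'
#' @param S1 QMC draws for the first estimation step (full climb).
#' @param S2 QMC draws for the second step (standard errors); `S2 >= S1`.
#' @param scramble_seed Optional seed for digital-shift scrambling of the
#'   Sobol draws (the same draws are reused across subjects and iterations
#'   so the objective is deterministic).
#' @param step2_max_iter Maximum Marquardt-Levenberg iterations in step 2
#'   while waiting for an invertible Hessian.
#' @param ml [ml_control()] settings for the optimizer.
#' @return A list of class `lsjm_control`.
#' @export
lsjm_control <- function(S1 = 500, S2 = 5000, scramble_seed = NULL,
                         step2_max_iter = 5,
                         ml = ml_control(hessian_method = "score",
                                         final_fd_hessian = FALSE)) {
  stopifnot(S2 >= S1)
  structure(list(S1 = as.integer(S1), S2 = as.integer(S2),
                 scramble_seed = scramble_seed,
                 step2_max_iter = step2_max_iter, ml = ml),
            class = "lsjm_control")
}

# Linear reparameterization used during the climb: the baseline level of
# each cause absorbs `center * alpha` for every association term, so the
# working baseline intercept is the log hazard at typical marker values
# rather than at marker value zero. For B-spline baselines the shift
# applies to every coefficient (partition of unity).
center_transform <- function(data, theta0) {
  map <- data$model$map
  Tmat <- diag(map$n)
  y <- data$bundle$y
  c_all <- c(value = if (length(y)) mean(y) else 0,
             slope = 0,
             sigma = exp(unname(theta0[map$slices$mu][1])))
  for (k in seq_len(map$K)) {
    a_names <- map$associations[[k]]
    a_idx <- map$slices[[paste0("alpha", k)]]
    b_idx <- map$slices[[paste0("baseline", k)]]
    zrows <- switch(map$baseline[k],
                    exponential = b_idx,
                    weibull = b_idx[2],
                    bsplines = b_idx)
    cc <- c_all[a_names]
    for (j in seq_along(a_idx)) {
      Tmat[zrows, a_idx[j]] <- Tmat[zrows, a_idx[j]] + cc[j]
    }
  }
  Tmat
}

# optimize fn over a subset of coordinates, the rest pinned at theta0
fit_with_fixed <- function(fn, theta0, free, control, ...) {
  wrap <- function(th_free, by_subject = FALSE) {
    th <- theta0
    th[free] <- th_free
    fn(th, by_subject = by_subject, ...)
  }
  res <- marquardt_levenberg(wrap, theta0[free], control)
  theta <- theta0
  theta[free] <- res$theta
  res$theta_full <- theta
  res
}

#' Preliminary location-scale mixed model
#'
#' Fits the longitudinal submodel alone (marker mean with random effects
#' and log-linear subject-specific residual SD, no event terms) by QMC
#' maximum likelihood. Used to obtain initial values for the joint fit and
#' to check that no random-effect variance is degenerate.
#'
#' @param marker Long-format marker data (`id`, `time`, `value`, ...).
#' @param design An [ls_design()].
#' @param events Optional event table; only used to carry covariates and
#'   follow-up times (no survival parameters are estimated).
#' @param re_structure `"independent"` or `"full"`.
#' @param cfg A [qmc_config()].
#' @param control An [ml_control()].
#' @return A list of class `lsmm`: structured `params`, flat `theta`,
#'   `loglik`, optimizer result `ml`, and the internal `data`.
#' @export
lsmm_fit <- function(marker, design, events = NULL,
                     re_structure = c("independent", "full"),
                     cfg = qmc_config(S = 500),
                     control = ml_control(hessian_method = "score",
                                          final_fd_hessian = FALSE)) {
  re_structure <- match.arg(re_structure)
  marker <- as.data.frame(marker)
  if (is.null(events)) {
    events <- dplyr::summarise(dplyr::group_by(marker, .data$id),
                               time = max(.data$time) + 1e-6, .groups = "drop")
    events$status <- 0L
  } else {
    events <- as.data.frame(events)
    events$status <- 0L
  }
  events$entry <- 0
  model <- lsjm_model(design, K = 1, baseline = "exponential",
                      associations = list("value"),
                      re_structure = re_structure)
  data <- prepare_data(model, marker, events)
  map <- model$map
  theta0 <- lmm_start(data)
  # pin the (irrelevant) survival parameters: alpha = 0 and a baseline so
  # small that the survival terms vanish numerically
  theta0[map$slices$alpha1] <- 0
  theta0[map$slices$baseline1] <- -1000
  free <- c(map$slices$beta, map$slices$mu, map$slices$chol)
  fn <- function(th, by_subject = FALSE) {
    total_loglik(data, th, cfg, engine = "cpp", by_subject = by_subject)
  }
  res <- fit_with_fixed(fn, theta0, free, control)
  theta <- res$theta_full
  params <- params_unflatten(theta, map)
  structure(list(params = params, theta = theta, map = map,
                 loglik = res$value, ml = res, data = data,
                 Sigma = cov_from_chol(params$L)),
            class = "lsmm")
}

# crude starting values for (beta, mu, chol) from a standard homogeneous
# mixed model
lmm_start <- function(data) {
  map <- data$model$map
  design <- data$model$design
  b <- data$bundle
  theta0 <- numeric(map$n)
  names(theta0) <- map$names
  df <- as.data.frame(b$Xl)
  xn <- paste0("x", seq_len(ncol(df)))
  names(df) <- xn
  df$.y <- b$y
  df$.id <- rep(seq_len(b$N), diff(b$off))
  zn <- xn[design$random_mean]
  form <- stats::as.formula(paste(
    ".y ~ 0 +", paste(xn, collapse = " + "),
    "+ (0 +", paste(zn, collapse = " + "), "| .id)"))
  beta <- NULL
  fit <- tryCatch(
    lme4::lmer(form, data = df,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.nobs.vs.nRE = "ignore")),
    error = function(e) NULL)
  nb <- map$nb
  if (!is.null(fit)) {
    beta <- unname(lme4::fixef(fit))
    Sb <- as.matrix(lme4::VarCorr(fit)$.id)[seq_len(nb), seq_len(nb),
                                            drop = FALSE]
    sig <- stats::sigma(fit)
  } else {
    lmf <- stats::lm(stats::as.formula(
      paste(".y ~ 0 +", paste(xn, collapse = " + "))), data = df)
    beta <- unname(stats::coef(lmf))
    sig <- stats::sigma(lmf)
    Sb <- diag(rep(sig^2, nb), nb)
  }
  theta0[map$slices$beta] <- beta
  mu0 <- numeric(map$q)
  mu0[1] <- log(max(sig, 1e-3))
  theta0[map$slices$mu] <- mu0
  Lb <- t(chol_psd(Sb + diag(1e-6 * max(diag(Sb), 1), nb)))
  Ltau <- diag(0.1, map$ntau)
  L <- matrix(0, map$r, map$r)
  L[seq_len(nb), seq_len(nb)] <- Lb
  L[nb + seq_len(map$ntau), nb + seq_len(map$ntau)] <- Ltau
  theta0[map$slices$chol] <- chol_collapse(map, L)
  theta0
}

#' Initial values for the joint model
#'
#' Runs the preliminary location-scale mixed model for `(beta, mu, Sigma)`
#' and cause-specific parametric survival fits (with all association
#' parameters at zero) for the baseline and covariate parameters. Warns if
#' any random-effect variance estimate is near zero, since associations on
#' that effect would then be unidentifiable.
#'
#' @param data An [prepare_data()] object.
#' @param cfg A [qmc_config()] for the preliminary fit.
#' @param control An [ml_control()].
#' @return Flat parameter vector of starting values.
#' @export
lsjm_init <- function(data, cfg = qmc_config(S = 250),
                      control = ml_control(hessian_method = "score",
                                           final_fd_hessian = FALSE,
                                           max_iter = 50)) {
  map <- data$model$map
  design <- data$model$design
  marker <- tibble::tibble(
    id = rep(data$ids, vapply(data$subjects, function(s) length(s$visit_times), 0L)),
    time = unlist(lapply(data$subjects, `[[`, "visit_times")),
    value = unlist(lapply(data$subjects, `[[`, "marker_values")))
  pre <- lsmm_fit(marker, design, events = data$events,
                  re_structure = map$re_structure, cfg = cfg,
                  control = control)
  theta0 <- numeric(map$n)
  names(theta0) <- map$names
  theta0[map$slices$beta] <- pre$theta[pre$map$slices$beta]
  theta0[map$slices$mu] <- pre$theta[pre$map$slices$mu]
  theta0[map$slices$chol] <- pre$theta[pre$map$slices$chol]

  v <- diag(pre$Sigma)
  labs <- c(paste0("b", seq_len(map$nb) - 1), paste0("tau", seq_len(map$ntau) - 1))
  # an effectively-degenerate variance: associations loading on this
  # effect would be unidentifiable
  small <- v < 2e-3
  if (any(small)) {
    warning("near-zero random-effect variance estimate for ",
            paste(labs[small], collapse = ", "),
            "; associations on these effects may be unidentifiable")
  }

  ev <- data$events
  for (k in seq_len(map$K)) {
    wn <- if (length(map$surv_covariates) >= k) {
      map$surv_covariates[[k]]
    } else character()
    sl_b <- map$slices[[paste0("baseline", k)]]
    sl_g <- map$slices[[paste0("gamma", k)]]
    init <- surv_init(ev, k, map$baseline[k], wn,
                      nb_spline = map$n_spline_coef[k])
    theta0[sl_b] <- init$baseline
    if (!is.null(sl_g)) theta0[sl_g] <- init$gamma
    theta0[map$slices[[paste0("alpha", k)]]] <- 0
  }
  theta0
}

# cause-specific parametric survival starting values (alpha = 0)
surv_init <- function(events, k, variant, covnames, nb_spline) {
  d <- sum(events$status == k)
  rate <- max(d, 0.5) / sum(events$time)
  gamma <- rep(0, length(covnames))
  if (variant == "bsplines") {
    return(list(baseline = rep(log(rate), nb_spline), gamma = gamma))
  }
  form <- if (length(covnames)) {
    stats::as.formula(paste("survival::Surv(time, status == k) ~",
                            paste(covnames, collapse = " + ")))
  } else {
    survival::Surv(time, status == k) ~ 1
  }
  fit <- tryCatch(
    survival::survreg(form, data = cbind(events, k = k),
                      dist = if (variant == "weibull") "weibull" else "exponential"),
    error = function(e) NULL)
  if (is.null(fit)) {
    baseline <- if (variant == "weibull") c(0, log(rate)) else log(rate)
    return(list(baseline = baseline, gamma = gamma))
  }
  cf <- stats::coef(fit)
  if (variant == "weibull") {
    sc <- fit$scale
    kappa <- 1 / sc
    zeta0 <- -cf[[1]] / sc
    if (length(covnames)) gamma <- -cf[-1] / sc
    list(baseline = c(log(kappa), zeta0), gamma = unname(gamma))
  } else {
    if (length(covnames)) gamma <- -cf[-1]
    list(baseline = -cf[[1]], gamma = unname(gamma))
  }
}

#' Fit the location-scale joint model
#'
#' Two-step quasi-Monte-Carlo maximum likelihood: step 1 climbs to
#' convergence with `S1` Sobol draws from initial values produced by
#' [lsjm_init()]; step 2 restarts from the step-1 estimate with `S2` draws
#' and iterates until the finite-difference Hessian is negative definite
#' and well conditioned (at least one iteration when `S2 > S1`). Standard
#' errors come from the step-2 Hessian; covariance-entry and Weibull-shape
#' standard errors are mapped to the natural scale by the delta method.
#'
#' @param marker Long-format marker table (`id`, `time`, `value`).
#' @param events One-row-per-subject event table (`id`, `entry`, `time`,
#'   `status`, covariates).
#' @param model An [lsjm_model()]; alternatively pass `design` plus the
#'   model arguments.
#' @param design,K,baseline,associations,re_structure Used to build the
#'   model when `model` is not supplied.
#' @param control An [lsjm_control()].
#' @param init Optional flat vector of starting values.
#' @param delayed_entry Apply the left-truncation correction.
#' @return An object of class `lsjm`.
#' @export
lsjm_fit <- function(marker, events, model = NULL, design = ls_design(),
                     K = 2, baseline = "weibull",
                     associations = list(c("value", "slope", "sigma")),
                     re_structure = c("independent", "full"),
                     control = lsjm_control(), init = NULL,
                     delayed_entry = FALSE) {
  if (is.null(model)) {
    model <- lsjm_model(design, K = K, baseline = baseline,
                        associations = associations,
                        re_structure = match.arg(re_structure))
  }
  data <- prepare_data(model, marker, events, delayed_entry = delayed_entry)
  lsjm_fit_data(data, control = control, init = init)
}

#' @rdname lsjm_fit
#' @param data A prepared [prepare_data()] object (alternative entry
#'   point).
#' @export
lsjm_fit_data <- function(data, control = lsjm_control(), init = NULL) {
  map <- data$model$map
  cfg1 <- qmc_config(S = control$S1, scramble_seed = control$scramble_seed)
  cfg2 <- qmc_config(S = control$S2, scramble_seed = control$scramble_seed)
  theta0 <- if (is.null(init)) lsjm_init(data) else init
  stopifnot(length(theta0) == map$n)

  # The baseline log-hazard level and the current-value / current-SD
  # association coefficients are nearly collinear when the marker level is
  # far from zero. The climb therefore runs on a linearly reparameterized
  # vector in which the association terms are centered at typical marker
  # values; the inverse map (exact, linear) restores the natural scale.
  Tmat <- center_transform(data, theta0)
  Tinv <- solve(Tmat)
  work0 <- drop(Tmat %*% theta0)

  fn1 <- function(th, by_subject = FALSE) {
    total_loglik(data, drop(Tinv %*% th), cfg1, engine = "cpp",
                 by_subject = by_subject)
  }
  ml1 <- control$ml
  ml1$final_fd_hessian <- FALSE
  step1 <- marquardt_levenberg(fn1, work0, ml1)

  fn2 <- function(th, by_subject = FALSE) {
    total_loglik(data, drop(Tinv %*% th), cfg2, engine = "cpp",
                 by_subject = by_subject)
  }
  work <- step1$theta
  step2_iter <- 0L
  H <- NULL
  value <- NULL
  if (control$S2 == control$S1) {
    dv <- fd_derivatives(fn1, work, step = control$ml$fd_step)
    H <- dv$hessian; grad <- dv$gradient; value <- dv$f0
  } else {
    # Newton iterations with the richer draw set, stopping once the
    # finite-difference Hessian is negative definite and well conditioned
    # (at least one step is always attempted). The first proposal reuses
    # the step-1 curvature; only the gradient uses the S2 draws.
    fstep <- control$ml$fd_step
    f2 <- fn2(work)
    g2 <- colSums(score_matrix(fn2, work, fstep))
    st <- ml_propose_step(fn2, work, g2, -step1$hessian, f2, control$ml)
    step2_iter <- 1L
    if (st$accepted) work <- st$theta
    dv <- fd_derivatives(fn2, work, step = fstep,
                         f0 = if (st$accepted) st$value else f2)
    H <- dv$hessian; grad <- dv$gradient; value <- dv$f0
    while (!hessian_usable(H) && step2_iter < control$step2_max_iter) {
      st <- ml_propose_step(fn2, work, dv$gradient, -dv$hessian, dv$f0,
                            control$ml)
      step2_iter <- step2_iter + 1L
      if (!st$accepted) break
      work <- st$theta
      dv <- fd_derivatives(fn2, work, step = fstep, f0 = st$value)
      H <- dv$hessian; grad <- dv$gradient; value <- dv$f0
    }
    if (!hessian_usable(H)) {
      warning("step-2 Hessian not invertible within the iteration budget; ",
              "reporting step-1 estimates with the step-1 Hessian")
      work <- step1$theta
      dv <- fd_derivatives(fn1, work, step = control$ml$fd_step)
      H <- dv$hessian; grad <- dv$gradient; value <- dv$f0
    }
  }
  theta <- drop(Tinv %*% work)
  theta_step1 <- drop(Tinv %*% step1$theta)
  # map derivatives back to the natural scale: theta = Tinv %*% work
  grad <- drop(t(Tmat) %*% grad)
  H <- t(Tmat) %*% H %*% Tmat

  Hm <- -(H + t(H)) / 2
  vcov <- tryCatch(solve(Hm), error = function(e) matrix(NA_real_, map$n, map$n))
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(pmax(diag(vcov), 0))
  rdm <- rdm_criterion(grad, Hm, map$n)
  params <- params_unflatten(theta, map)
  Sigma <- cov_from_chol(params$L)
  ci <- map$slices$chol
  Sigma_se <- delta_method_se(params$L, vcov[ci, ci, drop = FALSE],
                              chol_idx = map$chol_idx)

  structure(
    list(theta = stats::setNames(theta, map$names), params = params,
         map = map, data = data, loglik = value,
         hessian = H, vcov = vcov,
         se = stats::setNames(se, map$names),
         Sigma = Sigma, Sigma_se = Sigma_se,
         rdm = rdm,
         converged = c(step1$converged,
                       list(hessian = hessian_usable(H),
                            rdm_final = is.finite(rdm) &&
                              rdm < control$ml$eps_d)),
         n_iter = c(step1 = step1$n_iter, step2 = step2_iter),
         trace = step1$trace, control = control,
         init = theta0,
         theta_step1 = stats::setNames(theta_step1, map$names)),
    class = "lsjm")
}

#' @export
print.lsjm <- function(x, ...) {
  cat("Location-scale joint model fit\n")
  cat("  subjects:", length(x$data$subjects),
      " causes:", x$map$K,
      " parameters:", x$map$n, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " RDM:", format(x$rdm, digits = 3), "\n")
  cat("  iterations: step 1 =", x$n_iter[["step1"]],
      ", step 2 =", x$n_iter[["step2"]], "\n")
  cat("  converged:", x$converged$all && x$converged$hessian, "\n")
  invisible(x)
}

#' @export
logLik.lsjm <- function(object, ...) {
  structure(object$loglik, df = object$map$n, class = "logLik")
}

#' @export
vcov.lsjm <- function(object, ...) object$vcov
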