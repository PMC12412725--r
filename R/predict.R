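# Empirical-Bayes random-effect modes, dynamic cause-specific risk
# predictions with Monte-Carlo confidence bands, and marker prediction
# intervals.

# log posterior kernel of one subject's random effects
re_posterior_kernel <- function(subject, design, params, baselines, Sigma_inv,
                                nb) {
  function(re) {
    b <- re[seq_len(nb)]
    tau <- re[-seq_len(nb)]
    loglik_longitudinal_given_re(subject, design, params, b, tau) +
      loglik_event_given_re(subject, design, params, b, tau, baselines) -
      0.5 * drop(re %*% Sigma_inv %*% re)
  }
}

#' Empirical-Bayes random-effect modes
#'
#' For each subject, maximizes the conditional posterior
#' `f(Y_i | b, tau) f(T_i, delta_i | b, tau) f(b, tau)` over the random
#' effects with the same Marquardt-Levenberg routine used for estimation.
#' Subjects whose maximization fails fall back to the prior mean 0 with a
#' warning.
#'
#' @param fit An [lsjm_fit()] object.
#' @param ids Subject ids (default: all subjects in the fitted data).
#' @return A tibble with one row per subject: id, the mode of each random
#'   effect (`b0, b1, ..., tau0, ...`).
#' @export
empirical_bayes_modes <- function(fit, ids = NULL) {
  data <- fit$data
  if (is.null(ids)) ids <- data$ids
  idx <- match(ids, data$ids)
  if (anyNA(idx)) stop("unknown subject id(s)", call. = FALSE)
  design <- data$model$design
  params <- fit$params
  baselines <- baselines_from_params(data, params)
  map <- fit$map
  Sigma <- cov_from_chol(params$L)
  Sigma_inv <- solve(Sigma + diag(1e-10 * max(diag(Sigma)), nrow(Sigma)))
  ctrl <- ml_control(hessian_method = "fd", final_fd_hessian = FALSE,
                     max_iter = 60)
  res <- matrix(0, length(idx), map$r)
  fails <- 0L
  for (j in seq_along(idx)) {
    subject <- data$subjects[[idx[j]]]
    kern <- re_posterior_kernel(subject, design, params, baselines,
                                Sigma_inv, map$nb)
    ml <- tryCatch(marquardt_levenberg(kern, rep(0, map$r), ctrl),
                   error = function(e) NULL)
    if (is.null(ml)) {
      fails <- fails + 1L
    } else {
      res[j, ] <- ml$theta
    }
  }
  if (fails > 0) {
    warning(fails, " subject(s) fell back to the prior mean 0 ",
            "(empirical-Bayes maximization failed)")
  }
  colnames(res) <- c(paste0("b", seq_len(map$nb) - 1),
                     paste0("tau", seq_len(map$ntau) - 1))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(res))
}

# Precompute all node/design matrices for one subject's dynamic prediction
# at landmark s and horizon t (visits strictly before s form the history).
prep_predict_subject <- function(data, i, s, t) {
  design <- data$model$design
  subject <- data$subjects[[i]]
  keep <- subject$visit_times < s
  cov <- subject$covariates
  zi <- design$random_mean
  mi <- design$random_variance
  th <- subject$visit_times[keep]
  Xh <- mean_design(design, th, cov)
  Oh <- variance_design(design, th, cov)

  outer <- gk15_panel(s, s + t)
  rows <- function(tt) {
    list(X = mean_design(design, tt, cov),
         dX = mean_design(design, tt, cov, deriv = TRUE),
         O = variance_design(design, tt, cov))
  }
  ro <- rows(outer$t)
  tin <- numeric(225); win <- numeric(225)
  for (q in 1:15) {
    gkq <- gk15_panel(0, outer$t[q])
    tin[(q - 1) * 15 + 1:15] <- gkq$t
    win[(q - 1) * 15 + 1:15] <- gkq$w
  }
  ri <- rows(tin)
  gs <- gk15_panel(0, s)
  rs <- rows(gs$t)

  K <- data$model$K
  W <- vector("list", K); Bin <- vector("list", K)
  Bout <- vector("list", K); Bsn <- vector("list", K)
  for (k in seq_len(K)) {
    wn <- if (length(design$surv_covariates) >= k) {
      design$surv_covariates[[k]]
    } else character()
    W[[k]] <- if (length(wn)) {
      matrix(as.numeric(unlist(cov)[wn]), nrow = 1)
    } else matrix(0, 1, 0)
    tpl <- data$baseline_templates[[k]]
    if (tpl$variant == "bsplines") {
      bh <- baseline_hazard_spec("bsplines",
                                 pars = rep(0, length(tpl$knots) + 4),
                                 knots = tpl$knots, boundary = tpl$boundary)
      Bin[[k]] <- suppressMessages(bspline_log_basis(bh, tin))
      Bout[[k]] <- suppressMessages(bspline_log_basis(bh, outer$t))
      Bsn[[k]] <- suppressMessages(bspline_log_basis(bh, gs$t))
    } else {
      Bin[[k]] <- matrix(0, 0, 0); Bout[[k]] <- matrix(0, 0, 0)
      Bsn[[k]] <- matrix(0, 0, 0)
    }
  }
  list(nb = length(zi), ntau = length(mi),
       yh = subject$marker_values[keep],
       Xh = Xh, Zh = Xh[, zi, drop = FALSE],
       Oh = Oh, Mh = Oh[, mi, drop = FALSE],
       tout = outer$t, wout = outer$w,
       Xout = ro$X, dXout = ro$dX, Oout = ro$O,
       Zout = ro$X[, zi, drop = FALSE], dZout = ro$dX[, zi, drop = FALSE],
       Mout = ro$O[, mi, drop = FALSE],
       tin = tin, win = win,
       Xin = ri$X, dXin = ri$dX, Oin = ri$O,
       Zin = ri$X[, zi, drop = FALSE], dZin = ri$dX[, zi, drop = FALSE],
       Min = ri$O[, mi, drop = FALSE],
       tsn = gs$t, wsn = gs$w,
       Xsn = rs$X, dXsn = rs$dX, Osn = rs$O,
       Zsn = rs$X[, zi, drop = FALSE], dZsn = rs$dX[, zi, drop = FALSE],
       Msn = rs$O[, mi, drop = FALSE],
       W = W, Bin = Bin, Bout = Bout, Bsn = Bsn)
}

#' Dynamic cause-specific risk prediction
#'
#' Probability of experiencing cause `k` in `(s, s + t]` for a subject
#' event-free at the landmark `s`, given the marker history strictly
#' before `s` and the fitted (or supplied) parameters. The random-effect
#' integrals are QMC averages weighted by the history likelihood; the time
#' integral uses the 15-point Gauss-Kronrod rule.
#'
#' @param fit An [lsjm_fit()] object.
#' @param ids Subject ids (default: all subjects still at risk at `s`).
#' @param s Landmark time.
#' @param t Horizon length (prediction window `(s, s + t]`); `t <= 0`
#'   returns probability 0.
#' @param cause Cause index, or `NULL` for all causes.
#' @param cfg [qmc_config()] for the random-effect integral.
#' @param L Monte-Carlo replicates for the 95% confidence band (0 = no
#'   band). Parameters are drawn from `N(theta_hat, vcov)`; draws giving an
#'   invalid probability are redrawn and counted.
#' @param theta Optional flat parameter vector overriding the estimates
#'   (e.g. the generating truth).
#' @return A tibble: `id`, `s`, `t`, `cause`, `point`, and with `L > 0`
#'   `low`, `high`, `median` and `L`.
#' @export
predict_risk <- function(fit, s, t, cause = NULL, ids = NULL,
                         cfg = qmc_config(S = 500), L = 0, theta = NULL) {
  data <- fit$data
  map <- fit$map
  at_risk <- vapply(data$subjects, function(x) x$time > s, TRUE)
  if (is.null(ids)) {
    ids <- data$ids[at_risk]
  } else if (!all(ids %in% data$ids[at_risk])) {
    warning("dropping subject(s) not at risk at the landmark")
    ids <- intersect(ids, data$ids[at_risk])
  }
  causes <- if (is.null(cause)) seq_len(map$K) else cause
  theta_hat <- if (is.null(theta)) unname(fit$theta) else unname(theta)
  E <- qmc_normal_draws(cfg, map$r)

  rows <- list()
  for (id in ids) {
    i <- match(id, data$ids)
    if (t <= 0) {
      for (k in causes) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = id, s = s, t = t, cause = k, point = 0)
      }
      next
    }
    sd_ <- prep_predict_subject(data, i, s, t)
    for (k in causes) {
      pi_of <- function(th) {
        pp <- params_unflatten(th, map)
        nd <- predict_subject_cpp(par_for_cpp(pp, map), sd_, E, k)
        if (nd[2] <= 0) return(NA_real_)
        min(max(nd[1] / nd[2], 0), 1)
      }
      point <- pi_of(theta_hat)
      row <- tibble::tibble(id = id, s = s, t = t, cause = k, point = point)
      if (L > 0) {
        ci <- prediction_ci_draws(pi_of, theta_hat, fit$vcov, L)
        row$low <- ci[["low"]]; row$high <- ci[["high"]]
        row$median <- ci[["median"]]; row$L <- L
        row$n_redraws <- ci[["n_redraws"]]
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lsjm_prediction", class(out))
  out
}

# Monte-Carlo confidence interval: draw theta ~ N(theta_hat, V), recompute
# the prediction, take the 2.5 / 97.5 percentiles.
prediction_ci_draws <- function(pi_of, theta_hat, vcov, L) {
  stopifnot(L >= 100)
  ev <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE)
  ev$values <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(ev$values), length(ev$values))
  vals <- numeric(L)
  redraws <- 0L
  for (l in seq_len(L)) {
    repeat {
      th <- theta_hat + drop(A %*% stats::rnorm(length(theta_hat)))
      v <- pi_of(th)
      if (is.finite(v)) break
      redraws <- redraws + 1L
      if (redraws > 50 * L) stop("prediction CI: too many invalid draws",
                                 call. = FALSE)
    }
    vals[l] <- v
  }
  qs <- stats::quantile(vals, c(0.025, 0.5, 0.975), names = FALSE)
  c(low = qs[1], median = qs[2], high = qs[3], n_redraws = redraws)
}

#' Individual marker prediction band
#'
#' Predicted marker trajectory at the subject's empirical-Bayes modes,
#' with the pointwise band `mean +/- 1.96 sigma_i(t)` reflecting the
#' subject-specific, time-dependent residual SD.
#'
#' @param fit An [lsjm_fit()] object.
#' @param id Subject id.
#' @param t_grid Times at which to evaluate the band.
#' @param modes Optional precomputed [empirical_bayes_modes()] row for the
#'   subject.
#' @return A tibble: `id`, `time`, `fit`, `sigma`, `lower`, `upper`.
#' @export
marker_prediction_band <- function(fit, id, t_grid, modes = NULL) {
  data <- fit$data
  i <- match(id, data$ids)
  if (is.na(i)) stop("unknown subject id", call. = FALSE)
  design <- data$model$design
  map <- fit$map
  if (is.null(modes)) modes <- empirical_bayes_modes(fit, ids = id)
  re <- as.numeric(modes[1, -1])
  b <- re[seq_len(map$nb)]
  tau <- re[map$nb + seq_len(map$ntau)]
  cov <- data$subjects[[i]]$covariates
  m <- marker_mean(design, t_grid, fit$params$beta, b, cov)
  s <- residual_sd(design, t_grid, fit$params$mu, tau, cov)
  tibble::tibble(id = id, time = t_grid, fit = m, sigma = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s)
}
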