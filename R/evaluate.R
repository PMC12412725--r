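# Replication-level performance measures (bias, ESE, ASE, coverage),
# Monte-Carlo error, and Nelson-Aalen-based goodness of fit.

#' Simulation performance measures
#'
#' Per-parameter bias, empirical standard error (SD of the estimates
#' across replications), asymptotic standard error (mean of the
#' model-based SEs) and empirical coverage of the Wald
#' `estimate +/- z * se` interval.
#'
#' @param estimates R x m matrix (or data frame) of estimates, one row per
#'   replication.
#' @param ses Matching matrix of standard errors.
#' @param truth Length-m vector of true values.
#' @param level Nominal confidence level (default 0.95).
#' @param converged Optional logical vector; non-converged replications
#'   are excluded and counted.
#' @return A tibble: parameter, truth, mean, bias, ese, ase, cr (%),
#'   with replication counts as attributes `R` and `n_converged`.
#' @export
performance_measures <- function(estimates, ses, truth, level = 0.95,
                                 converged = NULL) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  R_all <- nrow(estimates)
  stopifnot(nrow(ses) == R_all, ncol(ses) == ncol(estimates),
            length(truth) == ncol(estimates))
  if (is.null(converged)) converged <- rep(TRUE, R_all)
  estimates <- estimates[converged, , drop = FALSE]
  ses <- ses[converged, , drop = FALSE]
  R <- nrow(estimates)
  stopifnot(R >= 2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  nm <- colnames(estimates)
  if (is.null(nm)) nm <- paste0("theta", seq_along(truth))
  mean_est <- colMeans(estimates)
  ese <- apply(estimates, 2, stats::sd)
  ase <- colMeans(ses)
  cover <- vapply(seq_along(truth), function(j) {
    mean(estimates[, j] - z * ses[, j] <= truth[j] &
           truth[j] <= estimates[, j] + z * ses[, j])
  }, 0)
  out <- tibble::tibble(
    parameter = nm, truth = unname(truth), mean = unname(mean_est),
    bias = unname(mean_est - truth), ese = unname(ese), ase = unname(ase),
    cr = 100 * unname(cover))
  attr(out, "R") <- R_all
  attr(out, "n_converged") <- R
  out
}

#' Monte-Carlo error of an empirical coverage rate
#'
#' `100 * sqrt(level * (1 - level) / R)`, the binomial standard error (in
#' percent) of a coverage estimate over `R` replications.
#'
#' @param level Nominal coverage probability.
#' @param R Number of replications.
#' @return Percent Monte-Carlo error.
#' @export
mc_error_coverage <- function(level, R) {
  stopifnot(level > 0, level < 1, R >= 1)
  100 * sqrt(level * (1 - level) / R)
}

#' Cause-specific Nelson-Aalen estimator
#'
#' Cumulative-hazard estimator `sum_{t_j <= t} d_kj / n_j` over the event
#' times of cause `k`, with `n_j` the number at risk; tied event times are
#' aggregated.
#'
#' @param times Observed times.
#' @param status Event indicator (0 censored, k = cause).
#' @param cause Cause of interest.
#' @return A tibble `time`, `n_risk`, `n_event`, `cumhaz`, with the step
#'   function as attribute `stepfun`.
#' @export
nelson_aalen <- function(times, status, cause = 1) {
  stopifnot(length(times) == length(status), all(times >= 0))
  et <- sort(unique(times[status == cause]))
  n_risk <- vapply(et, function(u) sum(times >= u), 0)
  n_event <- vapply(et, function(u) sum(times == u & status == cause), 0)
  ch <- cumsum(ifelse(n_risk > 0, n_event / n_risk, 0))
  out <- tibble::tibble(time = et, n_risk = n_risk, n_event = n_event,
                        cumhaz = ch)
  attr(out, "stepfun") <- if (length(et)) {
    stats::stepfun(et, c(0, ch))
  } else {
    function(t) rep(0, length(t))
  }
  out
}

#' Goodness of fit: model-based versus Nelson-Aalen cumulative hazard
#'
#' At each grid time, the mean over subjects still at risk of the model
#' cumulative hazard evaluated at their empirical-Bayes random-effect
#' modes, paired with the nonparametric Nelson-Aalen estimate; optionally
#' stratified by a categorical covariate of the event table.
#'
#' @param fit An [lsjm_fit()] object.
#' @param grid Evaluation times (default: up to 60 quantile-spaced event
#'   times per cause).
#' @param stratify Optional column name of the event table.
#' @param modes Optional precomputed [empirical_bayes_modes()].
#' @return A tibble: `cause`, `stratum`, `time`, `model`, `nelson_aalen`.
#' @export
gof_cumhaz_comparison <- function(fit, grid = NULL, stratify = NULL,
                                  modes = NULL) {
  data <- fit$data
  design <- data$model$design
  map <- fit$map
  baselines <- baselines_from_params(data, fit$params)
  if (is.null(modes)) modes <- empirical_bayes_modes(fit)
  re <- as.matrix(modes[, -1, drop = FALSE])
  times <- vapply(data$subjects, `[[`, 0, "time")
  status <- vapply(data$subjects, `[[`, 0L, "status")
  strata <- if (is.null(stratify)) {
    factor(rep("all", length(times)))
  } else {
    factor(data$events[[stratify]])
  }
  out <- list()
  for (k in seq_len(map$K)) {
    for (lv in levels(strata)) {
      sel <- strata == lv
      tt <- times[sel]; st <- status[sel]
      gk <- if (is.null(grid)) {
        ev <- sort(unique(tt[st == k]))
        if (length(ev) > 60) {
          stats::quantile(ev, probs = seq(0, 1, length.out = 60),
                          names = FALSE)
        } else ev
      } else grid
      if (!length(gk)) next
      na <- attr(nelson_aalen(tt, st, k), "stepfun")
      idx <- which(sel)
      # per-subject model cumulative hazard at the EB modes over the grid
      model_mat <- matrix(NA_real_, length(idx), length(gk))
      for (jj in seq_along(idx)) {
        i <- idx[jj]
        b <- re[i, seq_len(map$nb)]
        tau <- re[i, map$nb + seq_len(map$ntau)]
        cov <- data$subjects[[i]]$covariates
        at_risk <- gk <= times[i]
        model_mat[jj, at_risk] <- vapply(gk[at_risk], function(u) {
          cumulative_hazard(design, 0, u, fit$params, b, tau, k,
                            baselines, cov)
        }, 0)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        cause = k, stratum = lv, time = gk,
        model = colMeans(model_mat, na.rm = TRUE),
        nelson_aalen = na(gk))
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("lsjm_gof", class(res))
  res
}
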