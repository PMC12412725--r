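# broom-style tidiers for fitted joint models.

#' Tidy a fitted location-scale joint model
#'
#' One row per parameter on the reporting scale: Weibull shapes are mapped
#' back from the log scale and covariance entries of the random effects are
#' reported as `Sigma[i,j]` with delta-method standard errors.
#'
#' @param x An `lsjm` object.
#' @param include_covariance Append the random-effect covariance entries.
#' @param conf.level Level for the Wald confidence bounds.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`, `block`.
#' @export
tidy.lsjm <- function(x, include_covariance = TRUE, conf.level = 0.95, ...) {
  map <- x$map
  est <- unname(x$theta)
  se <- unname(x$se)
  term <- names(x$theta)
  block <- rep("longitudinal", map$n)
  block[map$slices$chol] <- "covariance_chol"
  for (k in seq_len(map$K)) {
    for (part in c("gamma", "alpha", "baseline")) {
      sl <- map$slices[[paste0(part, k)]]
      if (!is.null(sl)) block[sl] <- paste0("survival", k)
    }
  }
  # natural-scale Weibull shape via the delta method
  for (k in seq_len(map$K)) {
    if (map$baseline[k] == "weibull") {
      j <- map$slices[[paste0("baseline", k)]][1]
      est[j] <- exp(est[j])
      se[j] <- est[j] * se[j]
      term[j] <- paste0("kappa_", k)
    }
  }
  keep <- block != "covariance_chol"
  out <- tibble::tibble(term = term[keep], estimate = est[keep],
                        std.error = se[keep], block = block[keep])
  if (include_covariance) {
    S <- x$Sigma
    Sse <- x$Sigma_se
    labs <- c(paste0("b", seq_len(map$nb) - 1),
              paste0("tau", seq_len(map$ntau) - 1))
    ij <- which(lower.tri(S, diag = TRUE), arr.ind = TRUE)
    # keep only structurally free entries
    free <- matrix(FALSE, map$r, map$r)
    Sfree <- tcrossprod(chol_expand(x$map, seq_len(nrow(map$chol_idx))))
    free <- Sfree != 0
    ij <- ij[free[ij], , drop = FALSE]
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("Sigma[", labs[ij[, 1]], ",", labs[ij[, 2]], "]"),
      estimate = S[ij], std.error = Sse[ij], block = "covariance"))
  }
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  out$conf.low <- out$estimate - z * out$std.error
  out$conf.high <- out$estimate + z * out$std.error
  out[, c("term", "estimate", "std.error", "statistic", "p.value",
          "conf.low", "conf.high", "block")]
}

#' Glance at a fitted location-scale joint model
#'
#' @param x An `lsjm` object.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `BIC`, `nobs`, `n_subjects`,
#'   `n_events`, `n_parameters`, `n_iter_step1`, `n_iter_step2`, `rdm`,
#'   `converged`.
#' @export
glance.lsjm <- function(x, ...) {
  N <- length(x$data$subjects)
  nobs <- sum(vapply(x$data$subjects, function(s) length(s$visit_times), 0L))
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * x$map$n,
    BIC = -2 * x$loglik + log(N) * x$map$n,
    nobs = nobs, n_subjects = N,
    n_events = sum(vapply(x$data$subjects, `[[`, 0L, "status") > 0),
    n_parameters = x$map$n,
    n_iter_step1 = unname(x$n_iter[["step1"]]),
    n_iter_step2 = unname(x$n_iter[["step2"]]),
    rdm = x$rdm,
    converged = isTRUE(x$converged$all) && isTRUE(x$converged$hessian))
}
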