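# Parameter bookkeeping: the flat vector the optimizer sees versus the
# structured representation (fixed effects, Cholesky factor of the
# random-effect covariance, per-cause hazard parameters).

#' Parameter map for a location-scale joint model
#'
#' Fixes the layout of the flat parameter vector: marker fixed effects
#' `beta`, log-SD fixed effects `mu`, the free entries of the lower
#' Cholesky factor of the random-effect covariance, then per cause the
#' survival covariate coefficients `gamma`, the association coefficients
#' (current value, current slope, current SD) and the baseline-hazard
#' parameters. Weibull shapes travel as `log(kappa)` in the flat vector so
#' positivity needs no constraint.
#'
#' @param design An [ls_design()].
#' @param K Number of competing causes.
#' @param baseline Baseline variant per cause: `"exponential"`, `"weibull"`
#'   or `"bsplines"` (recycled if length 1).
#' @param n_spline_coef Number of B-spline coefficients per cause (interior
#'   knots + 4), only used for `"bsplines"`.
#' @param associations Per cause, which of `c("value", "slope", "sigma")`
#'   enter the hazard (recycled if a single vector).
#' @param re_structure `"independent"` (the mean-effects block `b` and the
#'   variance-effects block `tau` are uncorrelated) or `"full"`.
#' @return An object of class `lsjm_param_map`.
#' @export
param_map <- function(design, K = 2,
                      baseline = "weibull",
                      n_spline_coef = 7,
                      associations = list(c("value", "slope", "sigma")),
                      re_structure = c("independent", "full")) {
  re_structure <- match.arg(re_structure)
  baseline <- rep_len(baseline, K)
  n_spline_coef <- rep_len(n_spline_coef, K)
  if (!is.list(associations)) associations <- list(associations)
  associations <- rep_len(associations, K)
  for (a in associations) {
    if (!length(a) || !all(a %in% c("value", "slope", "sigma"))) {
      stop("each cause needs a non-empty association set from value/slope/sigma",
           call. = FALSE)
    }
  }
  nb <- length(design$random_mean)
  ntau <- length(design$random_variance)
  r <- nb + ntau

  chol_idx <- chol_indices(nb, ntau, re_structure)
  nm <- character(0)
  slices <- list()
  add <- function(label, names) {
    slices[[label]] <<- length(nm) + seq_along(names)
    nm <<- c(nm, names)
  }
  xb <- c(basis_names(design$mean_basis), design$mean_covariates)
  xo <- c(basis_names(design$variance_basis), design$variance_covariates)
  add("beta", paste0("beta[", xb, "]"))
  add("mu", paste0("mu[", xo, "]"))
  add("chol", paste0("chol[", chol_idx[, 1], ",", chol_idx[, 2], "]"))
  for (k in seq_len(K)) {
    gk <- design$surv_covariates
    gk <- if (length(gk) >= k) gk[[k]] else character()
    if (length(gk)) add(paste0("gamma", k), paste0("gamma", k, "[", gk, "]"))
    ak <- associations[[k]]
    add(paste0("alpha", k), paste0("alpha_", ak, "_", k))
    bl <- switch(baseline[k],
      exponential = "zeta0",
      weibull = c("log_kappa", "zeta0"),
      bsplines = paste0("eta", seq_len(n_spline_coef[k])),
      stop("unknown baseline variant: ", baseline[k], call. = FALSE))
    add(paste0("baseline", k), paste0(bl, "_", k))
  }
  structure(
    list(names = nm, n = length(nm), slices = slices,
         chol_idx = chol_idx, re_structure = re_structure,
         nb = nb, ntau = ntau, r = r, K = K,
         baseline = baseline, n_spline_coef = n_spline_coef,
         associations = associations,
         p = n_mean_coef(design), q = n_var_coef(design),
         surv_covariates = design$surv_covariates),
    class = "lsjm_param_map")
}

# (row, col) positions in the r x r lower-triangular factor corresponding to
# each free Cholesky parameter, column-major within each block.
chol_indices <- function(nb, ntau, re_structure) {
  r <- nb + ntau
  lower <- function(rows, cols) {
    out <- NULL
    for (j in cols) {
      for (i in rows) if (i >= j) out <- rbind(out, c(i, j))
    }
    out
  }
  if (re_structure == "full") {
    lower(seq_len(r), seq_len(r))
  } else {
    rbind(lower(seq_len(nb), seq_len(nb)),
          lower(nb + seq_len(ntau), nb + seq_len(ntau)))
  }
}

# Expand the free Cholesky parameters into the full r x r lower factor.
chol_expand <- function(map, chol_pars) {
  L <- matrix(0, map$r, map$r)
  L[map$chol_idx] <- chol_pars
  L
}

chol_collapse <- function(map, L) L[map$chol_idx]

#' Flatten / unflatten model parameters
#'
#' `params_flatten()` turns a structured parameter list into the flat vector
#' the optimizer works on; `params_unflatten()` inverts it. The two are a
#' bijection on the flat scale.
#'
#' @param params Structured parameters: `beta`, `mu`, `L` (lower Cholesky
#'   factor of the random-effect covariance) and `causes`, a list per cause
#'   with `gamma`, `alpha` (named subset of value/slope/sigma) and
#'   `baseline` (`variant` plus natural-scale `pars`).
#' @param map A [param_map()].
#' @param theta Flat numeric vector of length `map$n`.
#' @return A named numeric vector, or the structured list.
#' @export
params_flatten <- function(params, map) {
  theta <- numeric(map$n)
  s <- map$slices
  theta[s$beta] <- params$beta
  theta[s$mu] <- params$mu
  theta[s$chol] <- chol_collapse(map, params$L)
  for (k in seq_len(map$K)) {
    ck <- params$causes[[k]]
    gs <- s[[paste0("gamma", k)]]
    if (!is.null(gs)) theta[gs] <- ck$gamma
    theta[s[[paste0("alpha", k)]]] <- ck$alpha[map$associations[[k]]]
    bl <- ck$baseline$pars
    theta[s[[paste0("baseline", k)]]] <- switch(ck$baseline$variant,
      exponential = bl[["zeta0"]],
      weibull = c(log(bl[["kappa"]]), bl[["zeta0"]]),
      bsplines = bl)
  }
  stats::setNames(theta, map$names)
}

#' @rdname params_flatten
#' @export
params_unflatten <- function(theta, map) {
  stopifnot(length(theta) == map$n)
  s <- map$slices
  causes <- vector("list", map$K)
  for (k in seq_len(map$K)) {
    gs <- s[[paste0("gamma", k)]]
    ak <- map$associations[[k]]
    alpha <- c(value = 0, slope = 0, sigma = 0)
    alpha[ak] <- theta[s[[paste0("alpha", k)]]]
    blp <- theta[s[[paste0("baseline", k)]]]
    baseline <- switch(map$baseline[k],
      exponential = list(variant = "exponential",
                         pars = c(zeta0 = unname(blp[1]))),
      weibull = list(variant = "weibull",
                     pars = c(kappa = exp(unname(blp[1])),
                              zeta0 = unname(blp[2]))),
      bsplines = list(variant = "bsplines", pars = unname(blp)))
    causes[[k]] <- list(
      gamma = if (is.null(gs)) numeric(0) else unname(theta[gs]),
      alpha = alpha, baseline = baseline)
  }
  list(beta = unname(theta[s$beta]), mu = unname(theta[s$mu]),
       L = chol_expand(map, theta[s$chol]), causes = causes)
}

#' Random-effect covariance from its Cholesky factor
#'
#' @param chol Lower-triangular factor `L` as a matrix, or the column-major
#'   vector of its lower-triangular entries.
#' @return The covariance matrix `L %*% t(L)` (symmetric, positive
#'   semi-definite by construction).
#' @export
cov_from_chol <- function(chol) {
  L <- as_chol_matrix(chol)
  tcrossprod(L)
}

as_chol_matrix <- function(chol) {
  if (is.matrix(chol)) return(chol)
  r <- (sqrt(8 * length(chol) + 1) - 1) / 2
  if (abs(r - round(r)) > 1e-8) {
    stop("chol vector length is not a triangular number", call. = FALSE)
  }
  r <- as.integer(round(r))
  L <- matrix(0, r, r)
  L[lower.tri(L, diag = TRUE)] <- chol
  L
}

#' Delta-method standard errors for covariance entries
#'
#' Maps the estimated covariance matrix of the Cholesky parameters to
#' standard errors of the entries of `Sigma = L L'` via the gradient of the
#' map (`se^2 = g' V g` entrywise).
#'
#' @param chol Lower factor as matrix or lower-triangular vector.
#' @param V_chol Covariance matrix of the Cholesky parameters, in the same
#'   order as the vectorized lower triangle (or as `chol_idx` when a map is
#'   given).
#' @param chol_idx Optional 2-column matrix giving the (row, col) position
#'   of each Cholesky parameter; defaults to the full lower triangle,
#'   column-major.
#' @return A symmetric matrix of standard errors for the entries of `Sigma`.
#' @export
delta_method_se <- function(chol, V_chol, chol_idx = NULL) {
  L <- as_chol_matrix(chol)
  r <- nrow(L)
  if (is.null(chol_idx)) {
    chol_idx <- which(lower.tri(L, diag = TRUE), arr.ind = TRUE)[, c(1, 2)]
    chol_idx <- chol_idx[order(chol_idx[, 2], chol_idx[, 1]), , drop = FALSE]
  }
  npar <- nrow(chol_idx)
  stopifnot(nrow(V_chol) == npar, ncol(V_chol) == npar)
  ev <- eigen(V_chol, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    warning("V_chol is not positive semi-definite; delta-method SEs may be invalid")
  }
  se <- matrix(0, r, r)
  for (a in seq_len(r)) {
    for (b in seq_len(a)) {
      # d Sigma_ab / d L_uv = 1(a == u) L_bv + 1(b == u) L_av
      g <- numeric(npar)
      for (p in seq_len(npar)) {
        u <- chol_idx[p, 1]; v <- chol_idx[p, 2]
        g[p] <- (a == u) * L[b, v] + (b == u) * L[a, v]
      }
      se[a, b] <- se[b, a] <- sqrt(max(0, drop(t(g) %*% V_chol %*% g)))
    }
  }
  se
}
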