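# Finite-difference derivatives and the Marquardt-Levenberg ascent with
# diagonal Hessian inflation and relative-distance-to-maximum stopping.

fd_steps <- function(theta, step) pmax(step, step * abs(theta))

#' Finite-difference gradient and Hessian
#'
#' `fd_gradient()` uses central differences with per-coordinate step
#' `max(step, step * |theta_j|)`. `fd_hessian()` offers two schemes:
#' `"cross"` (forward cross-differences for off-diagonals, central for
#' diagonals; `m(m+3)/2 + 1` evaluations, symmetric by construction) and
#' `"central"` (full central differences, about `2 m^2` evaluations). The
#' result is symmetrized as `(H + t(H)) / 2`.
#'
#' @param fn Scalar function of a numeric vector.
#' @param theta Evaluation point.
#' @param step Relative finite-difference step.
#' @param scheme Hessian scheme.
#' @param ... Passed on to `fn`.
#' @return Gradient vector / symmetric Hessian matrix.
#' @export
fd_gradient <- function(fn, theta, step = 1e-4, ...) {
  m <- length(theta)
  h <- fd_steps(theta, step)
  g <- numeric(m)
  for (j in seq_len(m)) {
    g[j] <- fd_central_j(fn, theta, j, h[j], ...)
  }
  g
}

fd_central_j <- function(fn, theta, j, hj, ...) {
  for (attempt in 1:2) {
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    fp <- fn(tp, ...); fm <- fn(tm, ...)
    if (is.finite(fp) && is.finite(fm)) {
      return((fp - fm) / (2 * hj))
    }
    hj <- hj / 10
  }
  stop("non-finite values when differencing coordinate ", j, call. = FALSE)
}

#' @rdname fd_gradient
#' @export
fd_hessian <- function(fn, theta, step = 1e-4, scheme = c("cross", "central"),
                       ...) {
  scheme <- match.arg(scheme)
  fd_derivatives(fn, theta, step = step, scheme = scheme, ...)$hessian
}

# gradient + Hessian sharing evaluations; the workhorse of the optimizer
fd_derivatives <- function(fn, theta, step = 1e-4,
                           scheme = c("cross", "central"), f0 = NULL, ...) {
  scheme <- match.arg(scheme)
  m <- length(theta)
  h <- fd_steps(theta, step)
  if (is.null(f0)) f0 <- fn(theta, ...)
  if (!is.finite(f0)) stop("fn is not finite at theta", call. = FALSE)
  fp <- fm <- numeric(m)
  for (j in seq_len(m)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    fp[j] <- fn(tp, ...); fm[j] <- fn(tm, ...)
    if (!is.finite(fp[j]) || !is.finite(fm[j])) {
      h[j] <- h[j] / 10
      tp <- theta; tp[j] <- tp[j] + h[j]
      tm <- theta; tm[j] <- tm[j] - h[j]
      fp[j] <- fn(tp, ...); fm[j] <- fn(tm, ...)
      if (!is.finite(fp[j]) || !is.finite(fm[j])) {
        stop("non-finite values when differencing coordinate ", j,
             call. = FALSE)
      }
    }
  }
  g <- (fp - fm) / (2 * h)
  H <- matrix(0, m, m)
  diag(H) <- (fp - 2 * f0 + fm) / h^2
  if (m > 1) {
    for (j in seq_len(m - 1)) {
      for (k in (j + 1):m) {
        if (scheme == "cross") {
          tjk <- theta; tjk[j] <- tjk[j] + h[j]; tjk[k] <- tjk[k] + h[k]
          fjk <- fn(tjk, ...)
          H[j, k] <- H[k, j] <- (fjk - fp[j] - fp[k] + f0) / (h[j] * h[k])
        } else {
          tpp <- theta; tpp[j] <- tpp[j] + h[j]; tpp[k] <- tpp[k] + h[k]
          tpm <- theta; tpm[j] <- tpm[j] + h[j]; tpm[k] <- tpm[k] - h[k]
          tmp <- theta; tmp[j] <- tmp[j] - h[j]; tmp[k] <- tmp[k] + h[k]
          tmm <- theta; tmm[j] <- tmm[j] - h[j]; tmm[k] <- tmm[k] - h[k]
          H[j, k] <- H[k, j] <-
            (fn(tpp, ...) - fn(tpm, ...) - fn(tmp, ...) + fn(tmm, ...)) /
            (4 * h[j] * h[k])
        }
      }
    }
  }
  H <- (H + t(H)) / 2
  list(f0 = f0, gradient = g, hessian = H)
}

#' Optimizer settings
#'
#' @param eps_param Parameter-stability threshold (`max |delta theta|^2`).
#' @param eps_fn Function-stability threshold (`|delta loglik|`).
#' @param eps_d Relative-distance-to-maximum threshold
#'   (`g' H^-1 g / m < eps_d`).
#' @param max_iter Maximum Marquardt-Levenberg iterations.
#' @param fd_step Relative finite-difference step.
#' @param hessian_method `"fd"` (finite-difference Hessian each iteration)
#'   or `"score"` (cross-product of per-subject score vectors during the
#'   climb; the final curvature for standard errors is always the
#'   finite-difference Hessian).
#' @param final_fd_hessian Recompute the finite-difference Hessian at the
#'   optimum (needed for standard errors; can be disabled for intermediate
#'   fits).
#' @param phi0 Initial diagonal-inflation factor.
#' @param max_inflate Maximum number of inflation escalations.
#' @return A list of class `ml_control`.
#' @export
ml_control <- function(eps_param = 1e-4, eps_fn = 1e-4, eps_d = 1e-3,
                       max_iter = 100, fd_step = 1e-4,
                       hessian_method = c("fd", "score"),
                       final_fd_hessian = TRUE,
                       phi0 = 0.01, max_inflate = 12) {
  stopifnot(eps_param > 0, eps_fn > 0, eps_d > 0)
  structure(list(eps_param = eps_param, eps_fn = eps_fn, eps_d = eps_d,
                 max_iter = max_iter, fd_step = fd_step,
                 hessian_method = match.arg(hessian_method),
                 final_fd_hessian = final_fd_hessian,
                 phi0 = phi0, max_inflate = max_inflate),
            class = "ml_control")
}

# inflated negative Hessian:  Hm_ii + phi * ((1 - rho) |Hm_ii| + rho tr(Hm))
inflate_neg_hessian <- function(Hm, phi, rho) {
  Hm2 <- Hm
  diag(Hm2) <- diag(Hm) + phi * ((1 - rho) * abs(diag(Hm)) + rho * sum(diag(Hm)))
  Hm2
}

#' Marquardt-Levenberg maximization
#'
#' Maximizes `fn` by Newton steps on an inflated Hessian: the diagonal of
#' the (negated) Hessian is inflated by `phi * ((1 - rho) |H_ii| +
#' rho tr(H))`, with `(phi, rho)` escalated until the matrix is positive
#' definite and the step improves the objective; a step-halving safeguard
#' protects each accepted step. Iteration stops when parameter stability,
#' function stability and the relative distance to the maximum (RDM) all
#' fall below their thresholds.
#'
#' @param fn Scalar objective (log-likelihood) of a numeric vector. For
#'   `hessian_method = "score"` it must accept `by_subject = TRUE` and then
#'   return the vector of independent per-subject contributions.
#' @param theta0 Starting values.
#' @param control An [ml_control()].
#' @param ... Passed on to `fn`.
#' @return A list of class `ml_fit`: `theta`, `value`, `gradient`,
#'   `hessian` (of `fn` at the optimum), `vcov`, `se`, `rdm`, `converged`
#'   flags, `n_iter` and an iteration `trace`.
#' @export
marquardt_levenberg <- function(fn, theta0, control = ml_control(), ...) {
  theta <- theta0
  m <- length(theta)
  f0 <- fn(theta, ...)
  if (!is.finite(f0)) stop("fn not finite at theta0", call. = FALSE)
  use_score <- control$hessian_method == "score"
  trace <- list()
  conv <- list(parameters = FALSE, fn = FALSE, rdm = FALSE)
  rdm <- Inf
  iter <- 0
  d_theta2 <- Inf; d_fn <- Inf

  # The score-based (cross-product) Hessian climbs quickly but cannot
  # polish the optimum: once close (small RDM or stalled improvement),
  # switch to true finite-difference-Hessian Newton iterations, which
  # drive the gradient to zero in a handful of steps.
  polish <- FALSE
  deriv <- function(theta, f0) {
    if (use_score && !polish) {
      sc <- score_matrix(fn, theta, control$fd_step, ...)
      list(gradient = colSums(sc), hessian = -crossprod(sc), f0 = f0)
    } else {
      fd_derivatives(fn, theta, step = control$fd_step, scheme = "cross",
                     f0 = f0, ...)
    }
  }

  dv <- NULL
  dv_at <- NULL
  while (iter < control$max_iter) {
    iter <- iter + 1
    dv <- deriv(theta, f0)
    dv_at <- theta
    g <- dv$gradient
    Hm <- -dv$hessian                     # positive definite near the max
    rdm <- rdm_criterion(g, Hm, m)
    trace[[iter]] <- c(iter = iter, loglik = f0, rdm = rdm,
                       max_abs_grad = max(abs(g)))
    conv <- list(parameters = d_theta2 < control$eps_param,
                 fn = d_fn < control$eps_fn,
                 rdm = is.finite(rdm) && rdm < control$eps_d)
    if (all(unlist(conv)) && iter > 1) {
      iter <- iter - 1
      break
    }

    st <- ml_propose_step(fn, theta, g, Hm, f0, control, ...)
    accepted <- st$accepted
    if (accepted) {
      d_theta2 <- max((st$theta - theta)^2)
      d_fn <- st$value - f0
      theta <- st$theta; f0 <- st$value
      if (use_score && !polish &&
          (d_fn < control$eps_fn || (is.finite(rdm) && rdm < 0.02))) {
        polish <- TRUE
      }
    }
    if (!accepted) {
      if (use_score && !polish) {
        # the score-based direction found no uphill step; retry the
        # iteration with the true finite-difference Hessian
        polish <- TRUE
        iter <- iter - 1
        next
      }
      # no uphill step found: either we are at the maximum or inflation
      # failed to produce a usable direction
      if (is.null(tryCatch(chol(Hm), error = function(e) NULL)) &&
          max(abs(g)) > 1e-2) {
        stop("Marquardt-Levenberg: inflated Hessian unusable after maximum ",
             "inflation", call. = FALSE)
      }
      break
    }
  }

  if (control$final_fd_hessian) {
    dv <- fd_derivatives(fn, theta, step = control$fd_step, scheme = "cross",
                         f0 = f0, ...)
  } else if (is.null(dv) || !identical(dv_at, theta)) {
    # reuse the last in-loop derivatives when they are already at theta
    dv <- deriv(theta, f0)
  }
  g <- dv$gradient
  Hm <- -dv$hessian
  rdm <- rdm_criterion(g, Hm, m)
  conv <- list(parameters = d_theta2 < control$eps_param,
               fn = d_fn < control$eps_fn,
               rdm = is.finite(rdm) && rdm < control$eps_d)
  vcov <- tryCatch(solve(Hm), error = function(e) matrix(NA_real_, m, m))
  vcov <- (vcov + t(vcov)) / 2
  structure(
    list(theta = theta, value = f0, gradient = g, hessian = -Hm,
         vcov = vcov, se = sqrt(pmax(diag(vcov), 0)),
         rdm = rdm, converged = c(conv, list(all = all(unlist(conv)))),
         n_iter = iter,
         trace = tibble::as_tibble(do.call(rbind, trace))),
    class = "ml_fit")
}

# One Marquardt-Levenberg step proposal: escalate the diagonal inflation of
# the (negated) Hessian until it is positive definite, then step-halve
# until the objective improves.
ml_propose_step <- function(fn, theta, g, Hm, f0, control, ...) {
  # try the uninflated Newton step first; inflate only when the Hessian is
  # not negative definite or the step fails to improve
  phi <- 0; rho <- 0
  for (infl in seq_len(control$max_inflate)) {
    Hi <- inflate_neg_hessian(Hm, phi, rho)
    ch <- tryCatch(chol(Hi), error = function(e) NULL)
    if (!is.null(ch)) {
      d <- backsolve(ch, forwardsolve(t(ch), g))
      psi <- 1
      for (half in 1:10) {
        cand <- theta + psi * d
        fc <- fn(cand, ...)
        if (is.finite(fc) && fc > f0) {
          return(list(accepted = TRUE, theta = cand, value = fc))
        }
        psi <- psi / 2
      }
    }
    phi <- if (phi == 0) control$phi0 else phi * 10
    if (infl >= 4) rho <- min(1, rho + 0.5)
  }
  list(accepted = FALSE, theta = theta, value = f0)
}

rdm_criterion <- function(g, Hm, m) {
  ch <- tryCatch(chol(Hm), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  v <- forwardsolve(t(ch), g)
  sum(v^2) / m
}

# per-subject central-difference score matrix (N x m)
score_matrix <- function(fn, theta, step, ...) {
  m <- length(theta)
  h <- fd_steps(theta, step)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    cols[[j]] <- (fn(tp, by_subject = TRUE, ...) -
                    fn(tm, by_subject = TRUE, ...)) / (2 * h[j])
  }
  do.call(cbind, cols)
}

# negative-definiteness + conditioning check used by the two-step strategy
hessian_usable <- function(H, max_cond = 1e12) {
  ev <- eigen(-(H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0) && (max(ev) / min(ev) < max_cond)
}
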