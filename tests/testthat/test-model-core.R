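# Deterministic model quantities: trajectories, hazards, baselines,
# quadrature, covariance parameterization.

test_that("marker mean and slope match their closed forms", {
  d <- ls_design()
  expect_equal(marker_mean(d, 1, beta = c(142, 3), b = c(0, 0)), 145)
  expect_equal(marker_mean(d, 0, beta = c(142, 3), b = c(0, 0)), 142)
  expect_equal(marker_slope(d, c(0, 2.5, 4), beta = c(142, 3), b = c(0, 0)),
               rep(3, 3))
  d0 <- ls_design(mean_basis = time_poly(0), random_mean = 1)
  expect_equal(marker_slope(d0, c(0.3, 2), beta = 5, b = 0), c(0, 0))
  # quadratic design with random coefficients against a polynomial oracle
  dq <- ls_design(mean_basis = time_poly(2), random_mean = c(1, 2))
  beta <- c(140, 2.5, -0.3); b <- c(4, -1)
  tt <- c(0, 0.7, 1.9, 4.2)
  expect_equal(marker_mean(dq, tt, beta, b),
               (140 + 4) + (2.5 - 1) * tt - 0.3 * tt^2)
  h <- 1e-5
  slope_fd <- (marker_mean(dq, tt + h, beta, b) -
                 marker_mean(dq, tt - h, beta, b)) / (2 * h)
  expect_equal(marker_slope(dq, tt, beta, b), slope_fd, tolerance = 1e-6)
  expect_error(marker_mean(d, 1, beta = c(1, 2, 3), b = c(0, 0)), "length")
})

test_that("residual SD is the exponential of its linear predictor", {
  d <- ls_design()
  expect_equal(residual_sd(d, 0, mu = c(2.4, 0.05), tau = c(0, 0)),
               exp(2.4))
  expect_equal(residual_sd(d, 1.3, mu = c(0, 0), tau = c(0, 0)), 1)
  tt <- c(0, 1, 3.2)
  s <- residual_sd(d, tt, mu = c(2.4, 0.05), tau = c(0.1, -0.02))
  expect_equal(log(s), 2.5 + 0.03 * tt)
  expect_true(all(residual_sd(d, tt, mu = c(-30, 2), tau = c(0, 0)) > 0))
})

test_that("baseline hazard variants evaluate correctly", {
  wb1 <- baseline_hazard_spec("weibull", pars = c(kappa = 1, zeta0 = -2))
  expect_equal(baseline_hazard(wb1, c(0.5, 1, 7)), rep(exp(-2), 3))
  wb <- baseline_hazard_spec("weibull", pars = c(kappa = 1.12, zeta0 = -7))
  expect_equal(baseline_hazard(wb, 1), 1.12 * exp(-7))
  expect_equal(baseline_hazard(wb, 2), 1.12 * 2^0.12 * exp(-7))
  ex <- baseline_hazard_spec("exponential", pars = c(zeta0 = -3))
  expect_equal(baseline_hazard(ex, c(1, 10)), rep(exp(-3), 2))
  # cubic B-splines: equal coefficients give a flat hazard (partition of
  # unity); Q interior knots need Q + 4 coefficients
  bs <- baseline_hazard_spec("bsplines", pars = rep(0.7, 7),
                             knots = c(1, 2, 3), boundary = c(0, 5))
  tt <- seq(0.01, 4.99, length.out = 40)
  expect_equal(baseline_hazard(bs, tt), rep(exp(0.7), 40))
  expect_error(baseline_hazard_spec("bsplines", pars = rep(1, 6),
                                    knots = c(1, 2, 3), boundary = c(0, 5)),
               "Q \\+ 4")
  # constant continuation beyond the boundary knots
  bs2 <- baseline_hazard_spec("bsplines", pars = c(1, 2, 1.5, 0.5, 1, 2, 1),
                              knots = c(1, 2, 3), boundary = c(0, 5))
  expect_message(v <- baseline_hazard(bs2, 6), "boundary")
  expect_equal(v, suppressMessages(baseline_hazard(bs2, 5)))
})

test_that("hazard combines baseline, covariates and associations", {
  d <- ls_design()
  bl <- weibull_baselines(c(1.1, 1.32), c(-7, -4))
  p0 <- make_params(alpha = list(c(value = 0, slope = 0, sigma = 0),
                                 c(value = 0, slope = 0, sigma = 0)),
                    kappa = c(1.1, 1.32), zeta0 = c(-7, -4))
  t <- 2.3
  expect_equal(hazard(d, t, p0, b = c(1, 1), tau = c(0.5, 0), cause = 1, bl),
               baseline_hazard(bl[[1]], t))
  # cause-2 form with the generating associations against a scalar oracle
  p2 <- make_params(alpha = list(c(value = 0.02, slope = 0.01, sigma = 0.07),
                                 c(value = -0.01, slope = -0.14, sigma = 0.15)),
                    kappa = c(1.1, 1.32), zeta0 = c(-7, -4))
  b <- c(3, -0.4); tau <- c(0.05, 0.01)
  y <- 142 + 3 + (3 - 0.4) * t
  yp <- 3 - 0.4
  sg <- exp(2.4 + 0.05 + (0.05 + 0.01) * t)
  expect_equal(hazard(d, t, p2, b, tau, cause = 2, bl),
               1.32 * t^0.32 * exp(-4 - 0.01 * y - 0.14 * yp + 0.15 * sg))
  # dropping the sigma term equals setting its coefficient to zero
  p2b <- p2
  p2b$causes[[2]]$alpha[["sigma"]] <- 0
  expect_equal(hazard(d, t, p2b, b, tau, cause = 2, bl),
               1.32 * t^0.32 * exp(-4 - 0.01 * y - 0.14 * yp))
})

test_that("Gauss-Kronrod cumulative hazard matches closed forms and adaptive quadrature", {
  d <- ls_design()
  bl <- weibull_baselines(1.3, -4)
  p0 <- make_params(alpha = list(c(value = 0, slope = 0, sigma = 0)),
                    kappa = 1.3, zeta0 = -4)
  for (t1 in c(0.8, 3, 6)) {
    expect_equal(cumulative_hazard(d, 0, t1, p0, c(0, 0), c(0, 0), 1, bl),
                 t1^1.3 * exp(-4), tolerance = 1e-8)
  }
  ex <- list(baseline_hazard_spec("exponential", pars = c(zeta0 = log(0.2))))
  pex <- list(beta = c(142, 3), mu = c(2.4, 0.05), L = diag(4),
              causes = list(list(gamma = numeric(0),
                                 alpha = c(value = 0, slope = 0, sigma = 0),
                                 baseline = list(variant = "exponential",
                                                 pars = c(zeta0 = log(0.2))))))
  expect_equal(cumulative_hazard(d, 0, 4, pex, c(0, 0), c(0, 0), 1, ex),
               0.2 * 4, tolerance = 1e-12)
  # full model with random effects against adaptive quadrature
  p <- make_params()
  b <- c(5, -0.8); tau <- c(0.2, 0.03)
  qa <- stats::integrate(function(u) {
    hazard(d, u, p, b, tau, 1, weibull_baselines(1.1, -7))
  }, 0, 4.5, rel.tol = 1e-10)$value
  gk <- cumulative_hazard(d, 0, 4.5, p, b, tau, 1, weibull_baselines(1.1, -7))
  expect_lt(abs(gk - qa) / qa, 1e-6)
  # additivity over adjacent intervals and monotonicity
  g1 <- cumulative_hazard(d, 0, 2, p, b, tau, 1, weibull_baselines(1.1, -7))
  g2 <- cumulative_hazard(d, 2, 4.5, p, b, tau, 1, weibull_baselines(1.1, -7))
  expect_equal(g1 + g2, gk, tolerance = 1e-6)
  tt <- seq(0.5, 6, by = 0.5)
  lam <- vapply(tt, function(u) {
    cumulative_hazard(d, 0, u, p, b, tau, 1, weibull_baselines(1.1, -7))
  }, 0)
  expect_true(all(diff(lam) > 0))
  expect_error(cumulative_hazard(d, 2, 1, p, b, tau, 1,
                                 weibull_baselines(1.1, -7)), "t0 <= t1")
})

test_that("covariance round-trips through its Cholesky factor", {
  expect_equal(cov_from_chol(diag(3)), diag(3))
  sigma_c <- rbind(
    c(210.25, -15.95, 2.9, -0.145),
    c(-15.95, 9.05, -0.304, 0.067),
    c(2.9, -0.304, 0.1309, -0.0206),
    c(-0.145, 0.067, -0.0206, 0.0141))
  L <- t(chol(sigma_c))
  expect_equal(cov_from_chol(L), sigma_c, tolerance = 1e-12)
  expect_equal(cov_from_chol(L[lower.tri(L, diag = TRUE)]), sigma_c,
               tolerance = 1e-12)
})

test_that("delta-method SEs match parametric-bootstrap SEs on a 2x2 toy", {
  L0 <- rbind(c(2, 0), c(-0.7, 1.2))
  chol0 <- L0[lower.tri(L0, diag = TRUE)]
  V <- diag(c(0.02, 0.015, 0.01)^2)
  se <- delta_method_se(L0, V)
  expect_equal(se, t(se))
  set.seed(99)
  draws <- MASS::mvrnorm(40000, chol0, V)
  boots <- apply(draws, 1, function(ch) {
    Lb <- matrix(0, 2, 2); Lb[lower.tri(Lb, diag = TRUE)] <- ch
    tcrossprod(Lb)[c(1, 2, 4)]
  })
  bse <- apply(boots, 1, sd)
  expect_equal(unname(se[c(1, 2)][1]), bse[1], tolerance = 0.1)
  expect_equal(unname(se[2, 1]), bse[2], tolerance = 0.1)
  expect_equal(unname(se[2, 2]), bse[3], tolerance = 0.1)
  Vbad <- V; Vbad[1, 1] <- -0.01
  expect_warning(delta_method_se(L0, Vbad), "positive semi-definite")
})

test_that("flat and structured parameters are a bijection", {
  for (re in c("independent", "full")) {
    d <- ls_design(surv_covariates = list("trt", c("trt", "age")))
    map <- param_map(d, K = 2, baseline = c("weibull", "bsplines"),
                     n_spline_coef = 7,
                     associations = list(c("value", "sigma"),
                                         c("value", "slope", "sigma")),
                     re_structure = re)
    set.seed(5)
    theta <- rnorm(map$n)
    back <- params_flatten(params_unflatten(theta, map), map)
    expect_equal(unname(back), theta, tolerance = 1e-12)
    expect_equal(names(back), map$names)
    # Sigma built from the factor is symmetric PSD
    pp <- params_unflatten(theta, map)
    S <- cov_from_chol(pp$L)
    expect_equal(S, t(S))
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  }
})
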