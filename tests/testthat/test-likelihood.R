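# Marginal likelihood: conditional contributions, QMC integration,
# delayed entry, and equivalence with independent oracles.

test_that("longitudinal conditional log-likelihood matches Gaussian oracles", {
  d <- ls_design()
  p <- make_params(mu = c(0, 0))
  s1 <- make_subject(visits = 1, values = 145, time = 5, status = 0)
  expect_equal(loglik_longitudinal_given_re(s1, d, p, b = c(0, 0),
                                            tau = c(0, 0)),
               log(1 / sqrt(2 * pi)))
  # homogeneous variance equals an independent standard-normal computation
  set.seed(2)
  tt <- c(0, 0.5, 1, 2, 3)
  yy <- 142 + 3 * tt + rnorm(5, 0, 3)
  s2 <- make_subject(tt, yy, time = 5, status = 0)
  p2 <- make_params(mu = c(log(3), 0))
  manual <- sum(-log(3) - 0.5 * log(2 * pi) -
                  0.5 * ((yy - 142 - 3 * tt) / 3)^2)
  expect_equal(loglik_longitudinal_given_re(s2, d, p2, c(0, 0), c(0, 0)),
               manual)
  # unimodal in the deviation
  lls <- vapply(c(0, 1, 3, 9), function(dev) {
    s <- make_subject(1, 145 + dev, time = 5, status = 0)
    loglik_longitudinal_given_re(s, d, p, c(0, 0), c(0, 0))
  }, 0)
  expect_true(all(diff(lls) < 0))
  s0 <- make_subject(numeric(0), numeric(0), time = 5, status = 0)
  expect_equal(loglik_longitudinal_given_re(s0, d, p, c(0, 0), c(0, 0)), 0)
})

test_that("event conditional log-likelihood matches closed-form survival likelihoods", {
  d <- ls_design()
  # hazards numerically zero
  pz <- make_params(alpha = list(c(value = 0, slope = 0, sigma = 0)),
                    kappa = 1, zeta0 = -1000)
  blz <- weibull_baselines(1, -1000)
  s <- make_subject(c(0, 1), c(142, 145), time = 4, status = 0)
  expect_equal(loglik_event_given_re(s, d, pz, c(0, 0), c(0, 0), blz), 0)
  # single cause, constant hazard c, event at T: -cT + log(c)
  cc <- 0.23
  pc <- make_params(alpha = list(c(value = 0, slope = 0, sigma = 0)),
                    kappa = 1, zeta0 = log(cc))
  blc <- weibull_baselines(1, log(cc))
  se <- make_subject(c(0, 1), c(142, 145), time = 2.7, status = 1)
  expect_equal(loglik_event_given_re(se, d, pc, c(0, 0), c(0, 0), blc),
               -cc * 2.7 + log(cc), tolerance = 1e-10)
  # two Weibull causes without associations: closed-form competing risks
  p2 <- make_params(alpha = list(c(value = 0, slope = 0, sigma = 0),
                                 c(value = 0, slope = 0, sigma = 0)),
                    kappa = c(1.1, 1.3), zeta0 = c(-2, -1.5))
  bl2 <- weibull_baselines(c(1.1, 1.3), c(-2, -1.5))
  sv <- make_subject(c(0, 1), c(142, 145), time = 1.9, status = 2)
  closed <- -(1.9^1.1 * exp(-2) + 1.9^1.3 * exp(-1.5)) +
    log(1.3 * 1.9^0.3 * exp(-1.5))
  expect_equal(loglik_event_given_re(sv, d, p2, c(0, 0), c(0, 0), bl2),
               closed, tolerance = 1e-8)
})

test_that("QMC marginal log-likelihood matches a closed-form LMM marginal density", {
  # no event contribution, homogeneous variance: the marginal of Y is
  # multivariate normal with covariance Z Sigma_b Z' + sigma^2 I
  d <- ls_design()
  sig <- 4
  Sb <- rbind(c(25, -2), c(-2, 1.4))
  L <- matrix(0, 4, 4)
  L[1:2, 1:2] <- t(chol(Sb))
  p <- list(beta = c(142, 3), mu = c(log(sig), 0), L = L,
            causes = list(list(gamma = numeric(0),
                               alpha = c(value = 0, slope = 0, sigma = 0),
                               baseline = list(variant = "weibull",
                                               pars = c(kappa = 1,
                                                        zeta0 = -1000)))))
  bl <- weibull_baselines(1, -1000)
  set.seed(7)
  tt <- c(0, 0.5, 1, 2, 3.5)
  Z <- cbind(1, tt)
  y <- drop(142 + 3 * tt + Z %*% MASS::mvrnorm(1, c(0, 0), Sb) +
              rnorm(5, 0, sig))
  s <- make_subject(tt, y, time = 4, status = 0)
  V <- Z %*% Sb %*% t(Z) + sig^2 * diag(5)
  r <- y - (142 + 3 * tt)
  closed <- -0.5 * (5 * log(2 * pi) + determinant(V)$modulus[1] +
                      drop(r %*% solve(V, r)))
  got <- marginal_loglik_subject(s, d, p, bl, qmc_config(S = 5000))
  expect_equal(got, closed, tolerance = 1e-3)
})

test_that("QMC marginal agrees with adaptive quadrature for low-dimensional random effects", {
  # one random intercept, fixed variance, one cause with associations
  d1 <- design_1re()
  L1 <- diag(c(6, 0.2))
  p1 <- list(beta = c(140, 2), mu = 1.9, L = L1,
             causes = list(list(gamma = numeric(0),
                                alpha = c(value = 0.03, slope = 0,
                                          sigma = 0.1),
                                baseline = list(variant = "weibull",
                                                pars = c(kappa = 1.2,
                                                         zeta0 = -6)))))
  bl1 <- weibull_baselines(1.2, -6)
  s <- make_subject(c(0, 1, 2), c(139, 146, 141), time = 3.2, status = 1)
  cond <- function(b, tau) {
    loglik_longitudinal_given_re(s, d1, p1, b, tau) +
      loglik_event_given_re(s, d1, p1, b, tau, bl1)
  }
  # 2-D adaptive quadrature over (b0, tau0)
  oracle2 <- log(pracma::integral2(
    function(b, t) {
      v <- matrix(0, nrow(b), ncol(b))
      for (i in seq_along(b)) {
        v[i] <- exp(cond(b[i], t[i])) * dnorm(b[i], 0, 6) * dnorm(t[i], 0, 0.2)
      }
      v
    }, -30, 30, -1, 1, reltol = 1e-10, vectorized = TRUE)$Q)
  got <- marginal_loglik_subject(s, d1, p1, bl1, qmc_config(S = 4000))
  expect_equal(got, oracle2, tolerance = 1e-4)

  # strictly 1-D: variance random effect degenerate
  L1d <- diag(c(6, 0))
  p1d <- p1; p1d$L <- L1d
  oracle1 <- log(stats::integrate(function(b) {
    vapply(b, function(bb) exp(cond(bb, 0)) * dnorm(bb, 0, 6), 0)
  }, -40, 40, rel.tol = 1e-10)$value)
  got1 <- marginal_loglik_subject(s, d1, p1d, bl1, qmc_config(S = 4000))
  expect_equal(got1, oracle1, tolerance = 1e-4)
})

test_that("delayed-entry correction behaves per its contracts", {
  d <- ls_design()
  p <- make_params(alpha = list(c(value = 0, slope = 0, sigma = 0)),
                   kappa = 1, zeta0 = log(0.4))
  bl <- weibull_baselines(1, log(0.4))
  cfg <- qmc_config(S = 64)
  s0 <- make_subject(c(0, 1), c(142, 145), time = 4, status = 0, entry = 0)
  expect_equal(delayed_entry_correction(s0, d, p, bl, cfg), 0)
  # constant hazard without random effects in the hazard: log P = -c T0
  s1 <- make_subject(c(2, 3), c(148, 150), time = 4, status = 0, entry = 1.5)
  expect_equal(delayed_entry_correction(s1, d, p, bl, cfg), -0.4 * 1.5,
               tolerance = 1e-8)
  expect_lte(delayed_entry_correction(s1, d, p, bl, cfg), 0)
  sbad <- make_subject(c(2, 3), c(148, 150), time = 4, status = 0, entry = 5)
  expect_error(delayed_entry_correction(sbad, d, p, bl, cfg), "entry")
  # 1-D random effect against a quadrature oracle
  d1 <- design_1re()
  p1 <- list(beta = c(140, 2), mu = 1.9, L = diag(c(6, 0)),
             causes = list(list(gamma = numeric(0),
                                alpha = c(value = 0.03, slope = 0, sigma = 0),
                                baseline = list(variant = "weibull",
                                                pars = c(kappa = 1.2,
                                                         zeta0 = -6)))))
  bl1 <- weibull_baselines(1.2, -6)
  s2 <- make_subject(2.2, 150, time = 4, status = 0, entry = 2)
  oracle <- log(stats::integrate(function(b) {
    vapply(b, function(bb) {
      exp(-cumulative_hazard(d1, 0, 2, p1, bb, 0, 1, bl1)) * dnorm(bb, 0, 6)
    }, 0)
  }, -40, 40, rel.tol = 1e-10)$value)
  got <- delayed_entry_correction(s2, d1, p1, bl1, qmc_config(S = 4000))
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("total log-likelihood is additive, order-invariant, and engines agree", {
  fx <- small_a(n = 25, seed = 31)
  cfg <- qmc_config(S = 200)
  ll <- total_loglik(fx$data, fx$theta, cfg)
  by_sub <- total_loglik(fx$data, fx$theta, cfg, by_subject = TRUE)
  expect_equal(sum(by_sub), ll)
  llr <- total_loglik(fx$data, fx$theta, cfg, engine = "r")
  expect_equal(llr, ll, tolerance = 1e-5)
  # permuting subjects leaves the total unchanged
  perm <- sample(fx$sim$events$id)
  ev2 <- fx$sim$events[match(perm, fx$sim$events$id), ]
  d2 <- prepare_data(fx$model, fx$sim$marker, ev2)
  expect_equal(total_loglik(d2, fx$theta, cfg), ll, tolerance = 1e-10)
  # duplicated dataset doubles the total
  mk2 <- fx$sim$marker
  mk2b <- mk2; mk2b$id <- mk2b$id + 1000
  evb <- fx$sim$events; evb$id <- evb$id + 1000
  d3 <- prepare_data(fx$model, rbind(mk2, mk2b), rbind(fx$sim$events, evb))
  expect_equal(total_loglik(d3, fx$theta, cfg), 2 * ll, tolerance = 1e-9)
})

test_that("likelihood factorizes when the association parameters vanish", {
  # with alpha = 0 and homogeneous variance the joint likelihood is the
  # LMM marginal plus the parametric survival likelihood, separately
  fx <- small_a(n = 20, seed = 55)
  map <- fx$model$map
  theta <- fx$theta
  theta[map$slices$mu] <- c(log(11), 0)
  # degenerate tau block
  ci <- map$chol_idx
  chp <- theta[map$slices$chol]
  chp[ci[, 1] > 2] <- 0
  theta[map$slices$chol] <- chp
  for (k in 1:2) theta[map$slices[[paste0("alpha", k)]]] <- 0
  ll <- total_loglik(fx$data, theta, qmc_config(S = 5000))

  pp <- params_unflatten(theta, map)
  # longitudinal block: closed-form LMM marginal
  Sb <- cov_from_chol(pp$L)[1:2, 1:2]
  ll_lmm <- sum(vapply(fx$data$subjects, function(s) {
    n <- length(s$visit_times)
    if (n == 0) return(0)
    Z <- cbind(1, s$visit_times)
    V <- Z %*% Sb %*% t(Z) + 11^2 * diag(n)
    r <- s$marker_values - drop(Z %*% c(142, 3))
    -0.5 * (n * log(2 * pi) + determinant(V)$modulus[1] +
              drop(r %*% solve(V, r)))
  }, 0))
  # survival block: two-cause Weibull likelihood in closed form
  ll_surv <- sum(vapply(fx$data$subjects, function(s) {
    k1 <- pp$causes[[1]]$baseline$pars; k2 <- pp$causes[[2]]$baseline$pars
    v <- -(s$time^k1[["kappa"]] * exp(k1[["zeta0"]]) +
             s$time^k2[["kappa"]] * exp(k2[["zeta0"]]))
    if (s$status > 0) {
      kk <- pp$causes[[s$status]]$baseline$pars
      v <- v + log(kk[["kappa"]] * s$time^(kk[["kappa"]] - 1) *
                     exp(kk[["zeta0"]]))
    }
    v
  }, 0))
  expect_equal(ll, ll_lmm + ll_surv, tolerance = 1e-3 * abs(ll_lmm + ll_surv))
})

test_that("log-sum-exp stabilization keeps the likelihood finite", {
  fx <- small_a(n = 10, seed = 77)
  theta <- fx$theta
  map <- fx$model$map
  # push the linear predictors to extreme but representable magnitudes
  theta[map$slices$alpha1] <- c(0.3, 0.3, 0.3)
  ll <- total_loglik(fx$data, theta, qmc_config(S = 100))
  expect_true(is.finite(ll))
  expect_true(all(is.finite(total_loglik(fx$data, theta, qmc_config(S = 100),
                                         by_subject = TRUE))))
})
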