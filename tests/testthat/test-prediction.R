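# Empirical-Bayes modes, dynamic risk predictions with Monte-Carlo bands,
# and marker prediction intervals.

test_that("empirical-Bayes modes shrink to the prior without data and match a grid oracle", {
  sf <- small_fit()
  fit <- sf$fit
  # a subject with no visits censored immediately: prior dominates
  mk <- sf$sim$marker
  ev <- sf$sim$events
  ev2 <- rbind(ev, tibble::tibble(id = 9999, entry = 0, time = 1e-3,
                                  status = 0L))
  d2 <- prepare_data(sf$data$model, mk, ev2)
  fit2 <- fit; fit2$data <- d2
  eb0 <- empirical_bayes_modes(fit2, ids = 9999)
  expect_lt(max(abs(as.numeric(eb0[1, -1]))), 0.05)

  # 2-D grid oracle on a one-random-effect design
  d1 <- design_1re()
  p1 <- list(beta = c(140, 2), mu = 2, L = diag(c(8, 0.3)),
             causes = list(list(gamma = numeric(0),
                                alpha = c(value = 0.02, slope = 0,
                                          sigma = 0.05),
                                baseline = list(variant = "weibull",
                                                pars = c(kappa = 1.2,
                                                         zeta0 = -6)))))
  bl1 <- weibull_baselines(1.2, -6)
  s <- make_subject(c(0, 1, 2.5), c(150, 155, 149), time = 3.5, status = 1)
  Sinv <- solve(diag(c(64, 0.09)))
  kern <- function(b0, t0) {
    loglik_longitudinal_given_re(s, d1, p1, b0, t0) +
      loglik_event_given_re(s, d1, p1, b0, t0, bl1) -
      0.5 * drop(c(b0, t0) %*% Sinv %*% c(b0, t0))
  }
  gb <- seq(-25, 25, length.out = 101)
  gt <- seq(-1, 1, length.out = 81)
  vals <- outer(gb, gt, Vectorize(kern))
  ij <- which(vals == max(vals), arr.ind = TRUE)
  grid_mode <- c(gb[ij[1]], gt[ij[2]])
  ml <- marquardt_levenberg(function(re, by_subject = FALSE) kern(re[1], re[2]),
                            c(0, 0), ml_control(final_fd_hessian = FALSE))
  expect_lt(abs(ml$theta[1] - grid_mode[1]), diff(gb)[1])
  expect_lt(abs(ml$theta[2] - grid_mode[2]), diff(gt)[1])

  # shrinkage: EB intercepts are no larger than raw per-subject deviations
  eb <- empirical_bayes_modes(fit, ids = sf$data$ids[1:12])
  ols <- vapply(1:12, function(i) {
    s <- sf$data$subjects[[i]]
    mean(s$marker_values - (fit$params$beta[1] +
                              fit$params$beta[2] * s$visit_times))
  }, 0)
  expect_lt(mean(abs(eb$b0)), mean(abs(ols)) + 0.5)
})

test_that("dynamic predictions are probabilities, monotone in the horizon, and sum below one", {
  sf <- small_fit()
  fit <- sf$fit
  at_risk <- sf$data$ids[vapply(sf$data$subjects, function(s) s$time > 3, TRUE)]
  ids <- head(at_risk, 4)
  p0 <- predict_risk(fit, s = 3, t = 0, ids = ids, cfg = qmc_config(S = 100))
  expect_true(all(p0$point == 0))
  horizons <- c(0.5, 1, 2)
  prev <- rep(0, length(ids) * 2)
  for (h in horizons) {
    p <- predict_risk(fit, s = 3, t = h, ids = ids, cfg = qmc_config(S = 100))
    expect_true(all(p$point >= prev - 1e-10))
    expect_true(all(p$point >= 0 & p$point <= 1))
    tot <- tapply(p$point, p$id, sum)
    expect_true(all(tot <= 1))
    prev <- p$point
  }
  expect_warning(predict_risk(fit, s = 3, t = 1, ids = sf$data$ids[
    vapply(sf$data$subjects, function(s) s$time <= 3, TRUE)][1],
    cfg = qmc_config(S = 50)), "not at risk")
})

test_that("dynamic predictions match forward simulation from the generating model", {
  # homogeneous configuration: the prediction is a deterministic function
  # of the parameters and can be checked by brute-force forward simulation
  cfg <- scenario_config("B", n = 30, Sigma = diag(1e-12, 4))
  sim <- simulate_lsjm(config = cfg, seed = 27)
  model <- scenario_model(cfg)
  data <- prepare_data(model, sim$marker, sim$events)
  theta <- params_flatten(lsjoint:::truth_params(cfg), model$map)
  fit <- structure(list(theta = theta,
                        params = params_unflatten(theta, model$map),
                        map = model$map, data = data,
                        vcov = diag(1e-20, model$map$n)),
                   class = "lsjm")
  id <- data$ids[vapply(data$subjects, function(s) s$time > 3, TRUE)][1]
  s <- 3; t <- 2
  got <- predict_risk(fit, s = s, t = t, ids = id, cfg = qmc_config(S = 250))
  # forward simulation: latent cause-specific times given the (common)
  # zero random effects, conditioned on being event-free at s
  set.seed(5)
  M <- 50000
  lam <- function(tt, ck) {
    ck$kappa * tt^(ck$kappa - 1) *
      exp(ck$zeta0 +
            ck$alpha[["value"]] * (142 + 3 * tt) +
            ck$alpha[["slope"]] * 3 +
            ck$alpha[["sigma"]] * exp(2.4 + 0.05 * tt))
  }
  # invert the conditional cumulative hazards on a fine grid
  grid <- seq(s, 80, length.out = 6000)
  draw_cond <- function(ck) {
    cum <- cumsum(c(0, (lam(grid[-1] - diff(grid) / 2, ck)) * diff(grid)))
    Ls <- stats::integrate(lam, 0, s, ck = ck, rel.tol = 1e-10)$value
    e <- stats::rexp(M)               # -log U, conditional on T > s
    out <- stats::approx(cum, grid, xout = e, ties = "ordered")$y
    out[is.na(out)] <- Inf
    out
  }
  t1 <- draw_cond(cfg$causes[[1]])
  t2 <- draw_cond(cfg$causes[[2]])
  hit <- pmin(t1, t2) <= s + t & t1 < t2
  phat1 <- mean(hit)
  se1 <- sqrt(phat1 * (1 - phat1) / M)
  expect_lt(abs(got$point[got$cause == 1] - phat1), 3 * se1 + 0.003)
})

test_that("Monte-Carlo confidence bands bracket and collapse correctly", {
  sf <- small_fit()
  fit <- sf$fit
  id <- sf$data$ids[vapply(sf$data$subjects, function(s) s$time > 3, TRUE)][1]
  set.seed(31)
  p <- predict_risk(fit, s = 3, t = 2, cause = 1, ids = id,
                    cfg = qmc_config(S = 100), L = 150)
  expect_lte(p$low, p$median)
  expect_lte(p$median, p$high)
  expect_true(p$low >= 0 && p$high <= 1)
  # a vanishing parameter covariance collapses the interval on the point
  fit0 <- fit
  fit0$vcov <- matrix(0, fit$map$n, fit$map$n)
  set.seed(32)
  p0 <- predict_risk(fit0, s = 3, t = 2, cause = 1, ids = id,
                     cfg = qmc_config(S = 100), L = 120)
  expect_equal(p0$low, p0$point, tolerance = 1e-10)
  expect_equal(p0$high, p0$point, tolerance = 1e-10)
})

test_that("marker prediction bands track the subject-specific residual SD", {
  sf <- small_fit()
  fit <- sf$fit
  id <- sf$data$ids[1]
  eb <- empirical_bayes_modes(fit, ids = id)
  band <- marker_prediction_band(fit, id, t_grid = c(0, 1, 2, 3, 4),
                                 modes = eb)
  expect_equal(band$upper - band$fit, 1.96 * band$sigma)
  expect_equal(band$fit - band$lower, 1.96 * band$sigma)
  # width grows when the variance slope is positive at the modes
  slope <- fit$params$mu[2] + as.numeric(eb$tau1)
  if (slope > 0) expect_true(all(diff(band$sigma) > 0))
  # homogeneous model: constant width
  fit_h <- fit
  fit_h$params$mu <- c(fit$params$mu[1], 0)
  band_h <- marker_prediction_band(fit_h, id, t_grid = c(0, 2, 4),
                                   modes = tibble::tibble(id = id, b0 = 0,
                                                          b1 = 0, tau0 = 0,
                                                          tau1 = 0))
  expect_equal(diff(band_h$upper - band_h$lower), c(0, 0))
  # ~95% of future noisy observations fall in the band built at the truth
  set.seed(41)
  tt <- runif(4000, 0, 5)
  sigs <- exp(2.4 + 0.05 * tt)
  ys <- 142 + 3 * tt + rnorm(4000, 0, sigs)
  inside <- abs(ys - (142 + 3 * tt)) <= 1.96 * sigs
  expect_equal(mean(inside), 0.95, tolerance = 0.01)
})
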