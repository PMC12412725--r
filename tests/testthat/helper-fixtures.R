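# Shared fixtures, built lazily and cached for the session.

fixture_env <- function() {
  if (!exists(".lsjoint_fixture_env", envir = globalenv())) {
    assign(".lsjoint_fixture_env", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".lsjoint_fixture_env", envir = globalenv())
}

fixture <- function(name, builder) {
  env <- fixture_env()
  if (!exists(name, envir = env)) {
    assign(name, builder(), envir = env)
  }
  get(name, envir = env)
}

# a small scenario-A dataset plus prepared data and generating truth
small_a <- function(n = 40, seed = 421) {
  fixture(paste0("small_a_", n, "_", seed), function() {
    sim <- simulate_lsjm("A", n = n, seed = seed)
    model <- scenario_model(sim$config)
    data <- prepare_data(model, sim$marker, sim$events)
    list(sim = sim, model = model, data = data,
         theta = params_flatten(sim$truth, model$map))
  })
}

# single-random-effect design (random intercept only, fixed variance),
# used for quadrature-oracle comparisons
design_1re <- function() {
  ls_design(mean_basis = time_poly(1), variance_basis = time_poly(0),
            random_mean = 1, random_variance = 1)
}

# a subject record assembled by hand
make_subject <- function(visits, values, time, status, entry = 0,
                         covariates = list()) {
  list(id = 1L, entry = entry, time = time, status = as.integer(status),
       visit_times = visits, marker_values = values,
       covariates = covariates)
}

weibull_baselines <- function(kappa, zeta0) {
  lapply(seq_along(kappa), function(k) {
    baseline_hazard_spec("weibull", pars = c(kappa = kappa[k],
                                             zeta0 = zeta0[k]))
  })
}

# structured parameters with sensible small defaults
make_params <- function(beta = c(142, 3), mu = c(2.4, 0.05),
                        L = diag(c(14.4, 3, 0.1, 0.1)),
                        alpha = list(c(value = 0.02, slope = 0.01,
                                       sigma = 0.07)),
                        kappa = 1.1, zeta0 = -7) {
  causes <- lapply(seq_along(alpha), function(k) {
    list(gamma = numeric(0), alpha = alpha[[k]],
         baseline = list(variant = "weibull",
                         pars = c(kappa = kappa[k], zeta0 = zeta0[k])))
  })
  list(beta = beta, mu = mu, L = L, causes = causes)
}

# one small joint fit shared by the estimation / prediction / tidier tests
small_fit <- function() {
  fixture("small_fit", function() {
    sim <- simulate_lsjm("A", n = 100, seed = 14)
    data <- prepare_data(scenario_model(sim$config), sim$marker, sim$events)
    fit <- suppressWarnings(lsjm_fit_data(
      data, control = lsjm_control(S1 = 100, S2 = 300, step2_max_iter = 3)))
    list(sim = sim, data = data, fit = fit)
  })
}
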