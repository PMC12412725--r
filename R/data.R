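# Model specification and data preparation. `prepare_data()` validates the
# long marker table against the one-row-per-subject event table and
# precomputes every design matrix the likelihood needs (visit rows,
# Gauss-Kronrod nodes on [0, T_i], rows at T_i and, for delayed entry, nodes
# on [0, T0i]), so that likelihood evaluations are pure linear algebra.

#' Joint model specification
#'
#' Combines the longitudinal design with the survival-side choices: number
#' of competing causes, baseline-hazard family, association structure and
#' whether the mean and variance random effects are correlated.
#'
#' @param design An [ls_design()].
#' @param K Number of competing causes.
#' @param baseline `"exponential"`, `"weibull"` or `"bsplines"`, per cause.
#' @param n_knots Interior knot count for B-spline baselines (knots are
#'   placed at quantiles of the observed event times).
#' @param associations Per cause, subset of `c("value", "slope", "sigma")`.
#' @param re_structure `"independent"` or `"full"` random-effect covariance.
#' @return An object of class `lsjm_model`.
#' @export
lsjm_model <- function(design, K = 2, baseline = "weibull", n_knots = 3,
                       associations = list(c("value", "slope", "sigma")),
                       re_structure = c("independent", "full")) {
  re_structure <- match.arg(re_structure)
  map <- param_map(design, K = K, baseline = baseline,
                   n_spline_coef = n_knots + 4,
                   associations = associations, re_structure = re_structure)
  structure(list(design = design, K = K, map = map,
                 baseline = rep_len(baseline, K),
                 n_knots = rep_len(n_knots, K)),
            class = "lsjm_model")
}

#' Assemble and validate joint-model data
#'
#' @param model An [lsjm_model()].
#' @param marker Long-format tibble/data frame with columns `id`, `time`,
#'   `value` (plus any covariates named by the design; subject-level
#'   covariates are read from `events`).
#' @param events One row per subject: `id`, `entry`, `time`, `status`
#'   (0 = censored, `k` = cause k), plus covariate columns.
#' @param delayed_entry Include the left-truncation correction terms
#'   (entry-time survival) in the likelihood. Default `FALSE`.
#' @return An object of class `lsjm_data` carrying the validated records
#'   and precomputed design matrices.
#' @export
prepare_data <- function(model, marker, events, delayed_entry = FALSE) {
  stopifnot(inherits(model, "lsjm_model"))
  marker <- as.data.frame(marker)
  events <- as.data.frame(events)
  need_m <- c("id", "time", "value")
  need_e <- c("id", "time", "status")
  if (!all(need_m %in% names(marker))) {
    stop("marker table must have columns ", paste(need_m, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_e %in% names(events))) {
    stop("event table must have columns ", paste(need_e, collapse = ", "),
         call. = FALSE)
  }
  if (!"entry" %in% names(events)) events$entry <- 0
  for (cl in c("time", "value")) {
    if (!is.numeric(marker[[cl]])) {
      stop("marker column '", cl, "' must be numeric", call. = FALSE)
    }
  }
  if (anyDuplicated(events$id)) {
    stop("event table has duplicated subject ids: ",
         paste(unique(events$id[duplicated(events$id)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- !marker$id %in% events$id
  if (any(unknown)) {
    stop("marker rows with ids absent from the event table (rows ",
         paste(utils::head(which(unknown), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(events$status < 0 | events$status > model$K)) {
    stop("event status must lie in 0..K = 0..", model$K, call. = FALSE)
  }
  if (any(events$time <= 0)) {
    stop("observed event/censoring times must be positive", call. = FALSE)
  }
  if (any(events$entry < 0) || any(events$entry > events$time)) {
    stop("entry times must satisfy 0 <= entry <= time", call. = FALSE)
  }
  tmax <- events$time[match(marker$id, events$id)]
  late <- marker$time > tmax + 1e-10
  if (any(late)) {
    stop("marker rows after the subject's observed time (rows ",
         paste(utils::head(which(late), 5), collapse = ", "), ")",
         call. = FALSE)
  }

  design <- model$design
  ids <- events$id
  N <- length(ids)
  covnames <- unique(c(design$mean_covariates, design$variance_covariates,
                       unlist(design$surv_covariates)))
  missing_cov <- setdiff(covnames, names(events))
  if (length(missing_cov)) {
    stop("covariate column(s) missing from event table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }

  # resolve B-spline knots from observed event times
  templates <- vector("list", model$K)
  for (k in seq_len(model$K)) {
    if (model$baseline[k] == "bsplines") {
      et <- events$time[events$status == k]
      if (length(et) < 2) et <- events$time
      templates[[k]] <- list(variant = "bsplines",
                             knots = default_spline_knots(et, model$n_knots[k]),
                             boundary = c(0, max(events$time)))
    } else {
      templates[[k]] <- list(variant = model$baseline[k])
    }
  }

  subjects <- vector("list", N)
  for (i in seq_len(N)) {
    sel <- marker$id == ids[i]
    tt <- marker$time[sel]
    ord <- order(tt)
    vt <- tt[ord]
    if (any(diff(vt) <= 0)) {
      stop("visit times must be strictly increasing within subject ", ids[i],
           call. = FALSE)
    }
    cov <- if (length(covnames)) as.list(events[i, covnames, drop = FALSE]) else list()
    subjects[[i]] <- list(
      id = ids[i], entry = events$entry[i], time = events$time[i],
      status = as.integer(events$status[i]),
      visit_times = vt, marker_values = marker$value[sel][ord],
      covariates = cov)
  }

  out <- structure(
    list(model = model, subjects = subjects, ids = ids,
         events = tibble::as_tibble(events),
         delayed_entry = delayed_entry && any(events$entry > 0),
         baseline_templates = templates),
    class = "lsjm_data")
  out$bundle <- build_bundle(out)
  out
}

#' @export
print.lsjm_data <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) length(s$visit_times), 0L))
  tab <- table(factor(vapply(x$subjects, `[[`, 0L, "status"),
                      levels = 0:x$model$K))
  cat("<lsjm_data> ", length(x$subjects), " subjects, ", nobs,
      " marker observations\n", sep = "")
  cat("  events:", paste0("cause ", seq_len(x$model$K), " = ",
                          tab[-1], collapse = ", "),
      "| censored =", tab[1], "\n")
  invisible(x)
}

# instantiate per-cause baseline_hazard objects from structured parameters
baselines_from_params <- function(data, params) {
  lapply(seq_len(data$model$K), function(k) {
    tpl <- data$baseline_templates[[k]]
    bl <- params$causes[[k]]$baseline
    if (tpl$variant == "bsplines") {
      baseline_hazard_spec("bsplines", pars = bl$pars,
                           knots = tpl$knots, boundary = tpl$boundary)
    } else {
      baseline_hazard_spec(tpl$variant, pars = bl$pars)
    }
  })
}

# Flatten everything into contiguous matrices for the C++ likelihood.
build_bundle <- function(data) {
  design <- data$model$design
  K <- data$model$K
  subs <- data$subjects
  N <- length(subs)
  zi <- design$random_mean
  mi <- design$random_variance

  rows_at <- function(tt, cov) {
    list(X = mean_design(design, tt, cov),
         dX = mean_design(design, tt, cov, deriv = TRUE),
         O = variance_design(design, tt, cov))
  }

  nobs <- vapply(subs, function(s) length(s$visit_times), 0L)
  off <- c(0L, cumsum(nobs))
  y <- unlist(lapply(subs, `[[`, "marker_values"), use.names = FALSE)
  if (is.null(y)) y <- numeric(0)

  Xl <- dXl <- Ol <- NULL
  Xs <- dXs <- Os <- NULL
  tnodes <- wnodes <- numeric(15 * N)
  XT <- matrix(0, N, n_mean_coef(design))
  dXT <- matrix(0, N, n_mean_coef(design))
  OT <- matrix(0, N, n_var_coef(design))
  Xl_list <- vector("list", N); dXl_list <- vector("list", N)
  Ol_list <- vector("list", N)
  Xs_list <- vector("list", N); dXs_list <- vector("list", N)
  Os_list <- vector("list", N)

  has_entry <- data$delayed_entry
  t0nodes <- w0nodes <- if (has_entry) numeric(15 * N) else numeric(0)
  Xs0_list <- dXs0_list <- Os0_list <- if (has_entry) vector("list", N) else NULL

  for (i in seq_len(N)) {
    s <- subs[[i]]
    cov <- s$covariates
    if (nobs[i] > 0) {
      rl <- rows_at(s$visit_times, cov)
    } else {
      rl <- list(X = matrix(0, 0, n_mean_coef(design)),
                 dX = matrix(0, 0, n_mean_coef(design)),
                 O = matrix(0, 0, n_var_coef(design)))
    }
    Xl_list[[i]] <- rl$X; dXl_list[[i]] <- rl$dX; Ol_list[[i]] <- rl$O
    gk <- gk15_panel(0, s$time)
    idx <- (i - 1) * 15 + 1:15
    tnodes[idx] <- gk$t; wnodes[idx] <- gk$w
    rs <- rows_at(gk$t, cov)
    Xs_list[[i]] <- rs$X; dXs_list[[i]] <- rs$dX; Os_list[[i]] <- rs$O
    rT <- rows_at(s$time, cov)
    XT[i, ] <- rT$X; dXT[i, ] <- rT$dX; OT[i, ] <- rT$O
    if (has_entry) {
      gk0 <- gk15_panel(0, max(s$entry, 0))
      t0nodes[idx] <- gk0$t
      w0nodes[idx] <- if (s$entry > 0) gk0$w else rep(0, 15)
      r0 <- rows_at(gk0$t, cov)
      Xs0_list[[i]] <- r0$X; dXs0_list[[i]] <- r0$dX; Os0_list[[i]] <- r0$O
    }
  }
  Xl <- do.call(rbind, Xl_list); dXl <- do.call(rbind, dXl_list)
  Ol <- do.call(rbind, Ol_list)
  Xs <- do.call(rbind, Xs_list); dXs <- do.call(rbind, dXs_list)
  Os <- do.call(rbind, Os_list)

  Wk <- vector("list", K)
  Bs <- vector("list", K); BT <- vector("list", K); Bs0 <- vector("list", K)
  for (k in seq_len(K)) {
    wn <- if (length(design$surv_covariates) >= k) {
      design$surv_covariates[[k]]
    } else character()
    Wk[[k]] <- if (length(wn)) {
      as.matrix(data$events[, wn, drop = FALSE])
    } else matrix(0, N, 0)
    tpl <- data$baseline_templates[[k]]
    if (tpl$variant == "bsplines") {
      bh <- baseline_hazard_spec("bsplines",
                                 pars = rep(0, length(tpl$knots) + 4),
                                 knots = tpl$knots, boundary = tpl$boundary)
      Bs[[k]] <- suppressMessages(bspline_log_basis(bh, tnodes))
      BT[[k]] <- suppressMessages(
        bspline_log_basis(bh, vapply(subs, `[[`, 0, "time")))
      Bs0[[k]] <- if (has_entry) {
        suppressMessages(bspline_log_basis(bh, t0nodes))
      } else matrix(0, 0, 0)
    } else {
      Bs[[k]] <- matrix(0, 0, 0); BT[[k]] <- matrix(0, 0, 0)
      Bs0[[k]] <- matrix(0, 0, 0)
    }
  }

  list(
    N = N, K = K, nb = length(zi), ntau = length(mi),
    y = y, off = off,
    Xl = Xl, Zl = Xl[, zi, drop = FALSE], Ol = Ol,
    Ml = Ol[, mi, drop = FALSE],
    tnodes = tnodes, wnodes = wnodes,
    Xs = Xs, dXs = dXs, Zs = Xs[, zi, drop = FALSE],
    dZs = dXs[, zi, drop = FALSE], Os = Os, Ms = Os[, mi, drop = FALSE],
    XT = XT, dXT = dXT, ZT = XT[, zi, drop = FALSE],
    dZT = dXT[, zi, drop = FALSE], OT = OT, MT = OT[, mi, drop = FALSE],
    Tobs = vapply(subs, `[[`, 0, "time"),
    delta = vapply(subs, `[[`, 0L, "status"),
    entry = vapply(subs, `[[`, 0, "entry"),
    has_entry = has_entry,
    t0nodes = t0nodes, w0nodes = w0nodes,
    Xs0 = if (has_entry) do.call(rbind, Xs0_list) else matrix(0, 0, 0),
    dXs0 = if (has_entry) do.call(rbind, dXs0_list) else matrix(0, 0, 0),
    Os0 = if (has_entry) do.call(rbind, Os0_list) else matrix(0, 0, 0),
    Zs0 = if (has_entry) do.call(rbind, Xs0_list)[, zi, drop = FALSE] else matrix(0, 0, 0),
    dZs0 = if (has_entry) do.call(rbind, dXs0_list)[, zi, drop = FALSE] else matrix(0, 0, 0),
    Ms0 = if (has_entry) do.call(rbind, Os0_list)[, mi, drop = FALSE] else matrix(0, 0, 0),
    W = Wk, Bs = Bs, BT = BT, Bs0 = Bs0,
    variant = vapply(data$baseline_templates, function(x) {
      switch(x$variant, exponential = 0L, weibull = 1L, bsplines = 2L)
    }, 0L))
}

# lightweight per-subject record, used by the R reference likelihood,
# empirical-Bayes machinery and tests
subject_record <- function(data, i) data$subjects[[i]]
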