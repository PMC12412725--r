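# Time bases with analytic derivatives and the model design specification.

#' Polynomial time basis
#'
#' Builds the basis `1, t, t^2, ..., t^degree` together with its analytic
#' derivatives, for use in [ls_design()].
#'
#' @param degree Polynomial degree (0 = intercept only).
#' @return A list of basis elements, each with `fn`, `dfn` and `name`.
#' @export
time_poly <- function(degree = 1) {
  stopifnot(degree >= 0)
  lapply(0:degree, function(d) {
    list(
      fn = local({
        d <- d
        function(t) t^d
      }),
      dfn = local({
        d <- d
        if (d == 0) function(t) rep(0, length(t)) else function(t) d * t^(d - 1)
      }),
      name = if (d == 0) "1" else if (d == 1) "t" else paste0("t^", d)
    )
  })
}

#' Design specification for the location-scale joint model
#'
#' Describes how time and covariates map to the fixed-effect design `X(t)`
#' of the marker mean, the design `O(t)` of the log residual SD, and their
#' random-effect sub-designs `Z(t)` and `M(t)`. Time enters through basis
#' functions with analytic derivatives; covariates are subject-level
#' constants appended after the time columns (their time-derivative is zero).
#'
#' @param mean_basis Basis for the marker mean; default linear in time.
#' @param variance_basis Basis for the log residual SD; default linear.
#' @param random_mean Indices of `mean_basis` columns carrying random
#'   effects; must include the intercept column 1. Default: all basis
#'   columns.
#' @param random_variance Same for the variance basis.
#' @param mean_covariates,variance_covariates Names of subject-level
#'   covariate columns entering `X` / `O`.
#' @param surv_covariates List (one character vector per cause) of
#'   subject-level covariates entering the proportional-hazard models.
#' @return An object of class `ls_design`.
#' @export
ls_design <- function(mean_basis = time_poly(1),
                      variance_basis = time_poly(1),
                      random_mean = NULL,
                      random_variance = NULL,
                      mean_covariates = character(),
                      variance_covariates = character(),
                      surv_covariates = list()) {
  if (is.null(random_mean)) random_mean <- seq_along(mean_basis)
  if (is.null(random_variance)) random_variance <- seq_along(variance_basis)
  if (!1 %in% random_mean || !1 %in% random_variance) {
    stop("random_mean and random_variance must include the intercept column 1",
         call. = FALSE)
  }
  stopifnot(all(random_mean <= length(mean_basis)),
            all(random_variance <= length(variance_basis)))
  for (b in c(mean_basis, variance_basis)) {
    if (!is.function(b$fn) || !is.function(b$dfn)) {
      stop("every basis element needs fn and dfn (analytic derivative)",
           call. = FALSE)
    }
  }
  structure(
    list(mean_basis = mean_basis, variance_basis = variance_basis,
         random_mean = as.integer(random_mean),
         random_variance = as.integer(random_variance),
         mean_covariates = mean_covariates,
         variance_covariates = variance_covariates,
         surv_covariates = surv_covariates),
    class = "ls_design")
}

n_random <- function(design) {
  length(design$random_mean) + length(design$random_variance)
}

basis_names <- function(basis) vapply(basis, `[[`, "", "name")

# Evaluate a basis (or its derivative) at times t -> length(t) x n matrix
eval_basis <- function(basis, t, deriv = FALSE) {
  cols <- lapply(basis, function(b) if (deriv) b$dfn(t) else b$fn(t))
  m <- do.call(cbind, cols)
  colnames(m) <- basis_names(basis)
  m
}

# Full design row-block at times t: time-basis columns then covariates
# (constant over t; zero columns under deriv). covariates: named numeric.
design_matrix <- function(basis, t, covariates = NULL, covariate_names = character(),
                          deriv = FALSE) {
  m <- eval_basis(basis, t, deriv = deriv)
  if (length(covariate_names)) {
    vals <- unlist(covariates)[covariate_names]
    if (anyNA(vals)) {
      stop("missing covariate value(s): ",
           paste(covariate_names[is.na(vals)], collapse = ", "), call. = FALSE)
    }
    cv <- matrix(rep(if (deriv) 0 else vals, each = length(t)),
                 nrow = length(t),
                 dimnames = list(NULL, covariate_names))
    m <- cbind(m, cv)
  }
  m
}

mean_design <- function(design, t, covariates = NULL, deriv = FALSE) {
  design_matrix(design$mean_basis, t, covariates, design$mean_covariates, deriv)
}

variance_design <- function(design, t, covariates = NULL, deriv = FALSE) {
  design_matrix(design$variance_basis, t, covariates,
                design$variance_covariates, deriv)
}

n_mean_coef <- function(design) {
  length(design$mean_basis) + length(design$mean_covariates)
}
n_var_coef <- function(design) {
  length(design$variance_basis) + length(design$variance_covariates)
}
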