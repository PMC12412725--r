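# Reading and writing the delimited formats: long marker file, subject
# event file, parameter tables, predictions and serialized fits.

#' Read joint-model input files
#'
#' Both files are comma-separated with a header row. The marker file needs
#' columns `id`, `time`, `value`; the event file `id`, `time`, `status`
#' (and optionally `entry`); extra columns are carried as covariates.
#' Referential integrity and per-row validity are checked with explicit
#' diagnostics.
#'
#' @param marker_path,event_path File paths.
#' @return A list with tibbles `marker` and `events`.
#' @export
read_lsjm_inputs <- function(marker_path, event_path) {
  marker <- utils::read.csv(marker_path)
  events <- utils::read.csv(event_path)
  for (cl in c("id", "time", "value")) {
    if (!cl %in% names(marker)) {
      stop("marker file lacks column '", cl, "'", call. = FALSE)
    }
  }
  for (cl in c("id", "time", "status")) {
    if (!cl %in% names(events)) {
      stop("event file lacks column '", cl, "'", call. = FALSE)
    }
  }
  for (cl in c("time", "value")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(marker[[cl]]))))
    if (length(bad)) {
      stop("non-numeric '", cl, "' in marker rows ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  unknown <- which(!marker$id %in% events$id)
  if (length(unknown)) {
    stop("marker rows with unknown ids: rows ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  tmax <- events$time[match(marker$id, events$id)]
  late <- which(marker$time > tmax + 1e-10)
  if (length(late)) {
    stop("marker measurements after the observed time: rows ",
         paste(utils::head(late, 5), collapse = ", "), call. = FALSE)
  }
  list(marker = tibble::as_tibble(marker), events = tibble::as_tibble(events))
}

#' Write a simulated dataset to CSV files
#'
#' @param sim An [simulate_lsjm()] result.
#' @param marker_path,event_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_lsjm_inputs <- function(sim, marker_path, event_path) {
  utils::write.csv(sim$marker, marker_path, row.names = FALSE)
  utils::write.csv(sim$events, event_path, row.names = FALSE)
  invisible(c(marker_path, event_path))
}

#' Serialize / restore a fitted joint model as plain text
#'
#' `write_lsjm_fit()` writes the parameter table (name, estimate, SE) and
#' the full Hessian as CSV files under `dir` — enough, together with the
#' original data files and model specification, to re-run predictions
#' without refitting via `read_lsjm_fit()`.
#'
#' @param fit An [lsjm_fit()] object.
#' @param dir Output directory (created if needed).
#' @param data A [prepare_data()] object matching the original model/data.
#' @return `write_lsjm_fit()`: the directory, invisibly.
#'   `read_lsjm_fit()`: an `lsjm` object.
#' @export
write_lsjm_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(name = names(fit$theta), estimate = unname(fit$theta),
               se = unname(fit$se)),
    file.path(dir, "parameters.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$hessian),
                   file.path(dir, "hessian.csv"), row.names = FALSE)
  meta <- data.frame(key = c("loglik", "rdm", "n_iter_step1", "n_iter_step2",
                             "converged"),
                     value = c(fit$loglik, fit$rdm, fit$n_iter[["step1"]],
                               fit$n_iter[["step2"]],
                               as.numeric(fit$converged$all)))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_lsjm_fit
#' @export
read_lsjm_fit <- function(dir, data) {
  pt <- utils::read.csv(file.path(dir, "parameters.csv"))
  H <- as.matrix(utils::read.csv(file.path(dir, "hessian.csv")))
  dimnames(H) <- NULL
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  map <- data$model$map
  stopifnot(nrow(pt) == map$n)
  theta <- stats::setNames(pt$estimate, pt$name)
  Hm <- -(H + t(H)) / 2
  vcov <- tryCatch(solve(Hm), error = function(e) matrix(NA_real_, map$n, map$n))
  vcov <- (vcov + t(vcov)) / 2
  params <- params_unflatten(unname(theta), map)
  ci <- map$slices$chol
  structure(
    list(theta = theta, params = params, map = map, data = data,
         loglik = meta$value[meta$key == "loglik"],
         hessian = H, vcov = vcov,
         se = stats::setNames(pt$se, pt$name),
         Sigma = cov_from_chol(params$L),
         Sigma_se = delta_method_se(params$L, vcov[ci, ci, drop = FALSE],
                                    chol_idx = map$chol_idx),
         rdm = meta$value[meta$key == "rdm"],
         converged = list(all = meta$value[meta$key == "converged"] == 1,
                          hessian = hessian_usable(H)),
         n_iter = c(step1 = meta$value[meta$key == "n_iter_step1"],
                    step2 = meta$value[meta$key == "n_iter_step2"]),
         control = NULL),
    class = "lsjm")
}
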