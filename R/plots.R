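# ggplot2 displays for goodness of fit, dynamic predictions and marker
# bands.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot goodness of fit of the survival submodels
#'
#' Model-based mean cumulative hazard at the empirical-Bayes modes against
#' the Nelson-Aalen estimator, per cause (and stratum).
#'
#' @param object An `lsjm_gof` tibble from [gof_cumhaz_comparison()], or an
#'   `lsjm` fit (the comparison is computed first).
#' @param ... Passed to [gof_cumhaz_comparison()] when `object` is a fit.
#' @return A ggplot.
#' @export
autoplot.lsjm_gof <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("model", "nelson_aalen"),
                              names_to = "estimator", values_to = "cumhaz")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$cumhaz,
                                          colour = .data$estimator,
                                          linetype = .data$estimator)) +
    ggplot2::geom_step(data = ~dplyr::filter(.x, .data$estimator == "nelson_aalen")) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$estimator == "model")) +
    ggplot2::labs(x = "time (years)", y = "cumulative hazard",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
  if (length(unique(object$stratum)) > 1) {
    p + ggplot2::facet_grid(stratum ~ cause,
                            labeller = ggplot2::label_both)
  } else {
    p + ggplot2::facet_wrap(~cause, labeller = ggplot2::label_both)
  }
}

#' @rdname autoplot.lsjm_gof
#' @export
autoplot.lsjm <- function(object, ...) {
  autoplot.lsjm_gof(gof_cumhaz_comparison(object, ...))
}

#' Plot dynamic risk predictions
#'
#' @param object An `lsjm_prediction` tibble from [predict_risk()].
#' @param ... Unused.
#' @return A ggplot of predicted probabilities per subject and cause, with
#'   Monte-Carlo confidence bars when present.
#' @export
autoplot.lsjm_prediction <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = factor(.data$id), y = .data$point)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cause, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "subject", y = "predicted probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("low" %in% names(object)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$low, ymax = .data$high), width = 0.2)
  }
  p
}

#' Plot an individual marker prediction band
#'
#' @param fit An `lsjm` object.
#' @param id Subject id.
#' @param t_grid Evaluation times (default: a grid over the subject's
#'   follow-up).
#' @return A ggplot of the predicted trajectory, its 95% band and the
#'   observed measurements.
#' @export
plot_marker_band <- function(fit, id, t_grid = NULL) {
  i <- match(id, fit$data$ids)
  if (is.na(i)) stop("unknown subject id", call. = FALSE)
  subject <- fit$data$subjects[[i]]
  if (is.null(t_grid)) {
    t_grid <- seq(0, subject$time, length.out = 50)
  }
  band <- marker_prediction_band(fit, id, t_grid)
  obs <- tibble::tibble(time = subject$visit_times,
                        value = subject$marker_values)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$value), shape = 17) +
    ggplot2::labs(x = "time (years)", y = "marker") +
    ggplot2::theme_minimal()
}
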