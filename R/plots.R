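#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted release model over the data
#'
#' @param object A `release_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot release_fit
#' @export
autoplot.release_fit <- function(object, ...) {
  curve <- predict.release_fit(object)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$released_pct)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Time (min)", y = "Cumulative released (%)",
      title = sprintf("%s fit (adj R² = %.4f, AIC = %.2f)",
                      object$model_id, object$gof$r2_adjusted,
                      object$gof$aic)) +
    ggplot2::theme_minimal()
}

#' Plot all fitted models of a ranking against the data
#'
#' @param object A `release_ranking` from [rank_release_models()].
#' @param ... Unused.
#' @return A ggplot faceted by model, ordered by rank.
#' @method autoplot release_ranking
#' @export
autoplot.release_ranking <- function(object, ...) {
  fits <- attr(object, "fits")
  curves <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(predict.release_fit(f), model_id = f$model_id)
  })
  curves$model_id <- factor(curves$model_id, levels = object$model_id)
  data <- fits[[1]]$data
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time_min, y = .data$released_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = data, size = 0.8) +
    ggplot2::facet_wrap(~model_id) +
    ggplot2::labs(x = "Time (min)", y = "Cumulative released (%)") +
    ggplot2::theme_minimal()
}

#' Plot a predicted plasma concentration-time profile
#'
#' @param object A `plasma_prediction`.
#' @param ... Unused.
#' @return A ggplot with the Cmax/Tmax point marked.
#' @method autoplot plasma_prediction
#' @export
autoplot.plasma_prediction <- function(object, ...) {
  unit <- object$uir$concentration_unit
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$time_min, y = .data$concentration)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::annotate("point", x = object$metrics$tmax_min,
                      y = object$metrics$cmax, shape = 1, size = 3) +
    ggplot2::labs(x = "Time (min)",
                  y = sprintf("Predicted concentration (%s)", unit),
                  title = sprintf("Cmax = %.4g %s at Tmax = %.3g min",
                                  object$metrics$cmax, unit,
                                  object$metrics$tmax_min)) +
    ggplot2::theme_minimal()
}

#' Plot a permeation flux regression
#'
#' @param object A `flux_fit`.
#' @param full_data Optional full permeation table (with
#'   `cumulative_q_ug_per_cm2`) to show points outside the window.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flux_fit
#' @export
autoplot.flux_fit <- function(object, full_data = NULL, ...) {
  pts <- if (is.null(full_data)) object$data else full_data
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_min,
                                    y = .data$cumulative_q_ug_per_cm2)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = object$data, method = "lm",
                         formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::labs(
      x = "Time (min)", y = expression(Q ~ (mu * g ~ cm^-2)),
      title = sprintf("Jss = %.4g µg cm⁻² h⁻¹ (R² = %.4f)",
                      object$jss_ug_cm2_h, object$r_squared)) +
    ggplot2::theme_minimal()
}
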