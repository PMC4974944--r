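#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

cell_label <- function(theta, alpha) {
  factor(sprintf("θ=%.2g, α=%.2g", theta, alpha))
}

#' Plot methods for experiment results
#'
#' Box plots of the percentage error between estimated and true density,
#' in the style of the validation figures: one box per submodel cell
#' (accuracy experiment), per capture target (capture-number experiment),
#' per movement setting (movement experiment) or per parameter and error
#' (parameter-error experiment).
#'
#' @param object An experiment result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-grem
NULL

#' @rdname autoplot-grem
#' @method autoplot grem_accuracy
#' @export
autoplot.grem_accuracy <- function(object, ...) {
  d <- dplyr::mutate(object$results, cell = cell_label(.data$theta, .data$alpha))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = .data$pct_error,
                                  fill = .data$region)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "% error in density estimate",
                  fill = "submodel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot-grem
#' @method autoplot grem_captures
#' @export
autoplot.grem_captures <- function(object, ...) {
  d <- dplyr::mutate(object$results, cell = cell_label(.data$theta, .data$alpha))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_captures),
                                  y = .data$pct_error, fill = .data$region)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "number of captures", y = "% error in density estimate",
                  fill = "submodel") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-grem
#' @method autoplot grem_movement
#' @export
autoplot.grem_movement <- function(object, ...) {
  d <- dplyr::mutate(
    object$results,
    cell = cell_label(.data$theta, .data$alpha),
    setting = factor(sprintf("S=%.2g, A=%.2g", .data$stationary_prob,
                             .data$max_turn))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$setting, y = .data$pct_error,
                                  fill = .data$region)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "movement model", y = "% error in density estimate",
                  fill = "submodel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot-grem
#' @method autoplot grem_parameter_error
#' @export
autoplot.grem_parameter_error <- function(object, ...) {
  d <- dplyr::mutate(object$results, cell = cell_label(.data$theta, .data$alpha))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(100 * .data$rel_error),
                                  y = .data$pct_error)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(.data$parameter ~ .data$cell) +
    ggplot2::labs(x = "% error in parameter", y = "% error in density estimate") +
    ggplot2::theme_minimal()
}

#' Plot the profile width over approach angles
#'
#' Shows how the detectable cross-section presented to an approaching
#' animal varies with its approach angle, together with the mean profile
#' used by the estimator.
#'
#' @inheritParams is_detected
#' @param n Number of approach angles to evaluate.
#' @return A ggplot object.
#' @export
plot_profile_width <- function(sensor, signal, n = 721) {
  sensor <- as_sensor(sensor)
  signal <- as_signal(signal)
  gamma <- seq(0, 2 * pi, length.out = n)
  d <- tibble::tibble(gamma = gamma,
                      p = profile_width(gamma, sensor, signal))
  pb <- mean_profile_closed(sensor, signal)
  ggplot2::ggplot(d, ggplot2::aes(.data$gamma, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = pb$p_bar, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "approach angle (rad)", y = "profile width",
      subtitle = sprintf("mean profile %.4g (submodel %s)", pb$p_bar,
                         pb$region)
    ) +
    ggplot2::theme_minimal()
}
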