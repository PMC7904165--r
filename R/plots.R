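#' Plot an incursion profile
#'
#' The geometric incursion probability against the reduced displacement; the
#' inflection near `rho = 1/2` marks the typical distance to a Voronoi cell
#' boundary.
#'
#' @param object An [incursion_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.incursion_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$rho, y = .data$p)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression(rho), y = expression(p[inc](rho)),
                  title = "Geometric probability of incursion") +
    ggplot2::theme_minimal()
}

#' Plot a trackability report
#'
#' Measured incursion probabilities across sampling timescales with the
#' fitted logistic-in-log curve and the critical resampling factor `tau1`.
#'
#' @param object A [trackability()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trackability_report <- function(object, ...) {
  ser <- object$series[!is.na(object$series$P_inc), ]
  grid <- tibble(tau = exp(seq(log(min(ser$tau)), log(max(ser$tau)),
                               length.out = 200)))
  grid$P_inc <- predict(object$fit, grid$tau)
  gg <- ggplot2::ggplot(ser, ggplot2::aes(x = .data$tau, y = .data$P_inc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau), y = expression(P[inc](tau)),
                  subtitle = sprintf("L = %.3g, k = %.3g, tau0 = %.3g, tau1 = %.3g (%s)",
                                     object$fit$L, object$fit$k, object$fit$tau0,
                                     object$tau1, object$sampling_class)) +
    ggplot2::theme_minimal()
  if (is.finite(object$tau1))
    gg <- gg + ggplot2::geom_vline(xintercept = object$tau1,
                                   linetype = "dashed", colour = "grey40")
  gg
}

#' Plot the convergence history of the soft-parameter iteration
#'
#' One panel per soft parameter, value against iteration.
#'
#' @param object An [iterate_autoparams()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.autoparam_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "soft parameter value") +
    ggplot2::theme_minimal()
}

#' Plot trajectories
#'
#' Paths coloured by identity over the ROI, y axis flipped to match image
#' coordinates.
#'
#' @param object A `trajectory_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$id, colour = factor(.data$id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
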