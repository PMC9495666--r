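# ggplot2 visualisations for the main result types.

#' Plot the normalized energy-frequency law
#'
#' Scatter of the normalized pairs `(f_i/fm, Ekbar_i/Ekm)` with the model
#' prediction (slope-1 line through the origin, dashed) and the fitted
#' zero-intercept regression line.
#'
#' @param object A `gait_cycle_table` from [invariant_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_cycle_table <- function(object, ...) {
  fit <- slope_fit(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_rel, y = .data$ek_rel)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_abline(slope = fit$slope, intercept = 0,
                         colour = "black") +
    ggplot2::labs(
      x = expression(f[i] / f[m]),
      y = expression(bar(E)[k][i] / E[km]),
      title = sprintf("Zero-intercept slope %.3f [%.3f, %.3f]",
                      fit$slope, fit$conf_low, fit$conf_high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a phase-space attractor
#'
#' Mean `(Q, P)` limit-cycle loop with a band of plus/minus one bin-wise
#' standard deviation around each coordinate.
#'
#' @param object A `gait_attractor` from [mean_attractor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_attractor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q_mean, y = .data$p_mean)) +
    ggplot2::geom_path(ggplot2::aes(x = .data$q_mean - .data$q_sd,
                                    y = .data$p_mean - .data$p_sd),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_path(ggplot2::aes(x = .data$q_mean + .data$q_sd,
                                    y = .data$p_mean + .data$p_sd),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_path(colour = "darkgreen", linewidth = 0.8) +
    ggplot2::labs(x = "Q (m)", y = "P (m/s)",
                  title = sprintf("Mean attractor over %d cycles",
                                  attr(object, "n_cycles"))) +
    ggplot2::coord_fixed(ratio = diff(range(object$q_mean)) /
                           max(diff(range(object$p_mean)), 1e-12)) +
    ggplot2::theme_minimal()
}

#' Plot a DFA fluctuation function
#'
#' Log-log fluctuation function with the fitted scaling line; the slope is
#' the Hurst exponent.
#'
#' @param object A `gait_dfa` from [dfa()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_dfa <- function(object, ...) {
  h <- attr(object, "hurst")
  fit <- lm(log(fluctuation) ~ log(size), data = object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = exp(stats::fitted(fit))),
                       colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "window size n", y = "F(n)",
                  title = sprintf("DFA scaling exponent H = %.3f", h)) +
    ggplot2::theme_minimal()
}
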