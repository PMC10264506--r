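#' Plot the cost-effectiveness plane of a PSA
#'
#' Scatter of per-iteration incremental QALYs against incremental costs,
#' with the willingness-to-pay threshold as a reference line through the
#' origin.
#'
#' @param object An `ec_psa`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_psa <- function(object, ...) {
  it <- object$iterations
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (AUD)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("%d PSA iterations; dashed line WTP $%s/QALY",
                                     object$n_iter,
                                     format(object$wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ec_psa
#' @export
plot_ce_plane <- function(object, ...) autoplot.ec_psa(object, ...)

#' Plot a cost-effectiveness acceptability curve
#'
#' @param object An `ec_ceac` from [ceac()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wtp,
                                       y = .data$p_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (AUD/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ec_ceac
#' @export
plot_ceac <- function(object, ...) autoplot.ec_ceac(object, ...)

#' Plot a tornado diagram
#'
#' Horizontal bars spanning the ICER obtained with each parameter at its
#' lower and upper 95% bound, widest on top; the vertical line marks the
#' base-case ICER.
#'
#' @param object An `ec_tornado` from [tornado()].
#' @param top Show only the `top` widest bars (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_tornado <- function(object, top = NULL, ...) {
  dat <- if (is.null(top)) object else head(object, top)
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "icer_base"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (AUD/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ec_tornado
#' @export
plot_tornado <- function(object, top = NULL, ...) {
  autoplot.ec_tornado(object, top = top, ...)
}

#' Plot a time-horizon sweep
#'
#' @param object An `ec_sweep` from [horizon_sweep()].
#' @param ... Unused.
#' @return A ggplot of the ICER against the horizon with the WTP threshold.
#' @export
autoplot.ec_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$horizon, y = .data$icer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$dominant)) +
    ggplot2::labs(x = "Time horizon (years)", y = "ICER (AUD/QALY)",
                  title = "ICER by time horizon",
                  colour = "Dominant") +
    ggplot2::theme_minimal()
}

#' Plot a cohort trace
#'
#' Stacked-area occupancy of each health state over the model cycles.
#'
#' @param object An `ec_trace` (e.g. `run_arm(...)$trace`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_trace <- function(object, ...) {
  dat <- tidy(object)
  dat$state <- factor(dat$state, levels = health_states())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                    fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (years)", y = "Cohort fraction",
                  title = "Cohort trace") +
    ggplot2::theme_minimal()
}
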