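# ggplot2 displays mirroring the standard aggregometry-FDA figures: mean +
# velocity + acceleration panels, nano-effect contrast curves, and the phase
# plane with its zero-velocity reference line.

#' Plot a curve estimate with its confidence band
#'
#' @param x A `curve_estimate` from [predict_curve()] /
#'   [predict_condition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.curve_estimate <- function(x, ...) {
  m <- attr(x, "deriv_order") %||% 0
  ylab <- c("aggregation (%)", "velocity (%/min)",
            "acceleration (%/min^2)")[m + 1L]
  gg <- ggplot2::ggplot(as.data.frame(x), ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = estimate), linewidth = 0.7) +
    ggplot2::labs(x = "time (min)", y = ylab) +
    ggplot2::theme_minimal()
  if (m > 0)
    gg <- gg + ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  gg
}

#' Curve, velocity and acceleration panels for one fitted trace
#'
#' Stacks the order-0, 1 and 2 estimates of a penalized-spline fit into one
#' faceted display with pointwise bands and zero reference lines on the
#' derivative panels.
#'
#' @param fit A [fit_penalized_spline()] object.
#' @param grid Evaluation times (default training times).
#' @param level Band level.
#' @return A ggplot object; the plotted values are attached as attribute
#'   `"data"`.
#' @export
plot_fit_panels <- function(fit, grid = NULL, level = 0.95) {
  labs <- c("aggregation (%)", "velocity (%/min)", "acceleration (%/min^2)")
  dd <- do.call(rbind, lapply(0:2, function(m) {
    est <- predict_curve(fit, grid, m, level)
    cbind(panel = factor(labs[m + 1L], levels = labs), as.data.frame(est))
  }))
  gg <- ggplot2::ggplot(dd, ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = estimate), linewidth = 0.7) +
    ggplot2::geom_hline(data = data.frame(panel = factor(labs[2:3],
                                                         levels = labs),
                                          y = 0),
                        ggplot2::aes(yintercept = y), linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
  attr(gg, "data") <- dd
  gg
}

#' Nano-effect plot
#'
#' Displays excess (positive) or deficit (negative) percent aggregation
#' relative to a baseline, with a horizontal zero reference line. Two input
#' shapes are supported: a [estimate_nano_effect()] object (one dashed trace
#' per paired dose contrast \eqn{\hat h_s(t)} plus the solid overall mean
#' curve), or a [fit_dose_model()] with `baseline` naming a condition, in
#' which case every condition's fitted curve is plotted minus the baseline
#' condition's curve (the baseline traces itself as the zero line).
#'
#' @param x A `nano_effect` or `dose_model_fit` object.
#' @param baseline Baseline condition label (required for `dose_model_fit`
#'   input; for `nano_effect` input it is checked against the paired labels
#'   when given).
#' @param file Optional CSV path: the plotted values are written as a twin of
#'   the figure.
#' @return A ggplot object with the plotted values attached as attribute
#'   `"data"`.
#' @export
nano_effect_plot <- function(x, baseline = NULL, file = NULL) {
  if (inherits(x, "nano_effect")) {
    if (!is.null(baseline) &&
        !baseline %in% c(x$pairing$agonist, x$pairing$np))
      stop("unknown baseline label '", baseline, "'")
    dd <- as.data.frame(x)
  } else if (inherits(x, "dose_model_fit")) {
    if (is.null(baseline))
      stop("'baseline' condition label is required for dose_model_fit input")
    b <- .match_condition(x, baseline)
    grid <- sort(unique(x$times))
    Mb <- .condition_rows(x, b, grid, 0)
    dd <- do.call(rbind, lapply(seq_len(nrow(x$conditions)), function(d) {
      Mc <- .condition_rows(x, d, grid, 0) - Mb
      est <- drop(Mc %*% x$theta_scaled)
      se <- sqrt(pmax(rowSums((Mc %*% x$cov_scaled) * Mc), 0))
      data.frame(dose = x$conditions$label[d], time = grid,
                 estimate = est, se = se)
    }))
  } else stop("'x' must be a nano_effect or dose_model_fit object")

  dd$dose <- as.character(dd$dose)
  solid <- if (inherits(x, "nano_effect")) "overall" else baseline
  gg <- ggplot2::ggplot(dd, ggplot2::aes(x = time, y = estimate,
                                         colour = dose)) +
    ggplot2::geom_hline(yintercept = 0, colour = "black") +
    ggplot2::geom_line(ggplot2::aes(linetype = dose == solid,
                                    linewidth = dose == solid)) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 0.9,
                                               `FALSE` = 0.5),
                                    guide = "none") +
    ggplot2::labs(x = "time (min)",
                  y = "excess aggregation vs baseline (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  attr(gg, "data") <- dd
  if (!is.null(file)) write.csv(dd, file, row.names = FALSE)
  gg
}

#' Phase-plane plot
#'
#' Predicted velocity against predicted aggregation with the fitted law and a
#' zero-velocity reference line, the standard display for reading off steady
#' states (where the law crosses zero) and their stability (crossing
#' direction).
#'
#' @param points Data frame from [phase_points()].
#' @param law Optional fitted law (`phase_linear_fit` or `phase_smooth_fit`)
#'   drawn over the observed aggregation range, with its confidence band for
#'   the smooth law.
#' @return A ggplot object.
#' @export
phase_plane_plot <- function(points, law = NULL) {
  gg <- ggplot2::ggplot(points,
                        ggplot2::aes(x = aggregation, y = velocity)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "aggregation (%)", y = "velocity (%/min)") +
    ggplot2::theme_minimal()
  if (inherits(law, "phase_linear_fit")) {
    gg <- gg + ggplot2::geom_abline(intercept = law$gamma0,
                                    slope = law$gamma1, colour = "red3")
  } else if (inherits(law, "phase_smooth_fit")) {
    yy <- seq(law$range[1L], law$range[2L], length.out = 200)
    est <- predict_phase_law(law, yy)
    dd <- data.frame(aggregation = yy, velocity = est$estimate,
                     lower = est$lower, upper = est$upper)
    gg <- gg +
      ggplot2::geom_ribbon(data = dd,
                           ggplot2::aes(ymin = lower, ymax = upper),
                           fill = "grey70", alpha = 0.6) +
      ggplot2::geom_line(data = dd, colour = "red3", linewidth = 0.8)
  }
  gg
}
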