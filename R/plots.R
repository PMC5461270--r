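#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation
#'
#' Trunk lateral velocity against its command, foot contact ribbons, and —
#' when diagnostics were logged — the mobility indices and switching
#' coefficients of the three actuators.
#'
#' @param object a `sidestep_sim` object.
#' @param ... unused.
#' @return A patchwork of ggplots.
#' @export
autoplot.sidestep_sim <- function(object, ...) {
  tr <- object$trajectory
  p_vel <- ggplot2::ggplot(tr, ggplot2::aes(t, vx_trunk)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "time (s)", y = "trunk lateral velocity (m/s)") +
    ggplot2::theme_minimal()
  if ("vd_x" %in% names(tr)) {
    p_vel <- p_vel +
      ggplot2::geom_line(ggplot2::aes(y = vd_x), colour = "black",
                         linetype = 2)
  }
  contact <- tidyr::pivot_longer(
    dplyr::select(tr, t, right = grounded_r, left = grounded_l),
    c(right, left), names_to = "foot", values_to = "grounded")
  p_contact <- ggplot2::ggplot(contact,
                               ggplot2::aes(t, foot, fill = grounded)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  plots <- list(p_vel, p_contact)
  if (all(c("k_1", "a_1") %in% names(tr))) {
    mob <- tidyr::pivot_longer(dplyr::select(tr, t, k_1, k_2, k_3),
                               -t, names_to = "actuator", values_to = "k")
    p_mob <- ggplot2::ggplot(mob, ggplot2::aes(t, actuator, fill = k)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient(low = "white", high = "grey10",
                                   limits = c(0, 1)) +
      ggplot2::labs(x = "time (s)", y = NULL, fill = "mobility") +
      ggplot2::theme_minimal()
    coef <- tidyr::pivot_longer(dplyr::select(tr, t, a_1, a_2, a_3),
                                -t, names_to = "actuator", values_to = "a")
    coef$a <- factor(coef$a, levels = c(-1, -0.5, 0, 0.5, 1))
    p_coef <- ggplot2::ggplot(coef, ggplot2::aes(t, actuator, fill = a)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_manual(values = c(`-1` = "blue",
                                            `-0.5` = "lightblue",
                                            `0` = "green3",
                                            `0.5` = "orange", `1` = "red"),
                                 drop = FALSE) +
      ggplot2::labs(x = "time (s)", y = NULL, fill = "a") +
      ggplot2::theme_minimal()
    plots <- c(plots, list(p_mob, p_coef))
  }
  patchwork::wrap_plots(plots, ncol = 1)
}

#' Plot a timing sweep
#'
#' Reaching time against the switch timing, coloured by the contact group at
#' the switch instant; failed trials (if any) are marked at the top.
#'
#' @param object a `sidestep_sweep` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sidestep_sweep <- function(object, ...) {
  tr <- dplyr::mutate(object$trials,
                      group = ifelse(trailing_stance, "trailing-leg stance",
                                     "other"))
  ggplot2::ggplot(tr, ggplot2::aes(t_switch, reach_time, colour = group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "direction-change command time (s)",
                  y = "reaching time (s)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of normalized peak foot heights
#'
#' @param peaks tibble from [peak_heights()].
#' @param binwidth histogram bin width on the normalized height axis.
#' @return A ggplot.
#' @export
plot_peak_heights <- function(peaks, binwidth = 0.02) {
  ggplot2::ggplot(peaks, ggplot2::aes(height_norm, fill = foot)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "dodge",
                            boundary = 0) +
    ggplot2::labs(x = "peak foot height / trunk height", y = "count") +
    ggplot2::theme_minimal()
}

#' Step-interval series plot
#'
#' @param intervals `intervals` tibble from [step_intervals()].
#' @return A ggplot.
#' @export
plot_step_intervals <- function(intervals) {
  ggplot2::ggplot(intervals, ggplot2::aes(step, interval, colour = foot)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "step number", y = "step interval (s)") +
    ggplot2::theme_minimal()
}
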