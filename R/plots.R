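# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a command waveform
#'
#' @param w A `command_waveform`.
#' @param window Shade the diastolic-depolarization window (default TRUE).
#' @param top_threshold Take-off threshold used for the shading, V/s.
#' @return A ggplot object.
#' @export
plot_waveform <- function(w, window = TRUE, top_threshold = 0.5) {
  stopifnot(inherits(w, "command_waveform"))
  p <- ggplot2::ggplot(w, ggplot2::aes(.data$time_ms, .data$vm_mV)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Time (ms)", y = expression(V[m] ~ "(mV)"))
  if (window) {
    dd <- detect_dd_window(w, top_threshold = top_threshold)
    p <- p + ggplot2::annotate(
      "rect", xmin = dd$t_mdp, xmax = dd$t_mdp + dd$dd_duration,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' @describeIn run_ap_clamp Plot the final-cycle If trace with the diastolic
#'   charge area shaded.
#' @param object A `qf_result`.
#' @param ... Unused.
#' @export
autoplot.qf_result <- function(object, ...) {
  tr <- object$if_trace
  win <- object$window
  shade <- tr[tr$time_ms >= win$t_mdp &
              tr$time_ms < win$t_mdp + win$dd_duration, ]
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_ms, .data$i_f_pA)) +
    ggplot2::geom_area(data = shade, fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Time (ms)", y = expression(I[f] ~ "(pA)"),
      title = sprintf("Diastolic If charge: %.3f pC", object$qf_pC)
    )
}

#' @describeIn simulate_cell Plot the membrane-potential trace (final 5 s by
#'   default).
#' @param object A `san_sim`.
#' @param window_s Final window to display, s.
#' @param ... Unused.
#' @export
autoplot.san_sim <- function(object, window_s = 5, ...) {
  tr <- object$trace
  tr <- tr[tr$time_s >= max(tr$time_s) - window_s, ]
  ggplot2::ggplot(tr, ggplot2::aes(.data$time_s, .data$vm_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = expression(V[m] ~ "(mV)"))
}

#' @describeIn fit_line Scatter plot of the points with the dashed OLS line.
#' @param object A `qf_fit`.
#' @param ... Unused.
#' @export
autoplot.qf_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(Q[f] ~ "(pC)"), y = "Rate (beats/min)",
      subtitle = sprintf("R² = %.2f%s", object$r_squared,
                         if (is.na(object$p_value)) ""
                         else sprintf(", p = %.3g", object$p_value))
    )
}
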