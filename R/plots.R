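#' Plot a quit-time distribution
#'
#' Quit-probability mass over time, with the survival curve overlaid on a
#' secondary scale-free layer if `survival = TRUE`.
#'
#' @param object A [quit_time_distribution()].
#' @param survival Overlay the survival curve \eqn{P_{wait}(t)} (rescaled to
#'   the mass axis).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.quit_time_distribution <- function(object, survival = FALSE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$p_quit)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "time since waiting began (s)", y = "quit probability mass",
      title = sprintf("Quit-time distribution (prior reward probability %.2g)",
                      attr(object, "p_reward"))
    ) +
    ggplot2::theme_minimal()
  if (survival) {
    scale <- max(object$p_quit)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$p_wait * scale),
                                linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a stimulation effect curve
#'
#' Mean quit time without and with the stimulation prior boost across the
#' swept levels, with the shift in a lower panel-like colour encoding.
#'
#' @param object A [stim_effect_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stim_effect_curve <- function(object, ...) {
  vary <- attr(object, "vary") %||% "prior"
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("level", "mean_no_stim_s", "mean_stim_s")],
    -"level", names_to = "stim", values_to = "mean_quit_s"
  )
  long$stim <- factor(long$stim, c("mean_no_stim_s", "mean_stim_s"),
                      c("no activation", "activation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$mean_quit_s,
                                     colour = .data$stim)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c("no activation" = "#e6a800",
                                            "activation" = "#2166ac")) +
    ggplot2::labs(
      x = if (vary == "prior") "reward probability" else "timing uncertainty sigma (s)",
      y = "mean quit time (s)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of per-test waiting-time ratios by condition
#'
#' @param ratios Output of [waiting_time_ratio()].
#' @return A ggplot object.
#' @export
plot_waiting_ratios <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$condition, y = .data$ratio)) +
    ggplot2::geom_boxplot(fill = "#9ecae1") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "waiting-time ratio (activation / no activation)") +
    ggplot2::theme_minimal()
}
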