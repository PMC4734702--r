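# Plotting: panel figures in the layout used for this circuit's results
# (plan activities on top, salience/sensory maps as channel-by-time
# heatmaps, stimuli at the bottom).

.heat_panel <- function(trace, prefix, channels, title) {
  cols <- paste0(prefix, ".i", channels)
  d <- tidyr::pivot_longer(
    trace[, c("time", cols)], -"time",
    names_to = "ch", values_to = "activity"
  )
  d$ch <- as.integer(sub(".*\\.i", "", d$ch))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$ch, fill = pmax(.data$activity, 0))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred", name = NULL) +
    ggplot2::labs(y = title, x = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(legend.position = "none")
}

#' Panel figure of a simulation trace
#'
#' Stacks the plan-map activities (feed in blue, fear in red), the two
#' amygdala salience maps, the sensory cortex / TRN / thalamus heatmaps,
#' and the delivered stimuli and reinforcers, sharing the time axis.
#'
#' @param object An `amygate_trace`.
#' @param ... Unused.
#' @return A patchwork of ggplots.
#' @export
autoplot.amygate_trace <- function(object, ...) {
  trace <- object
  N <- attr(trace, "schedule")$n_channels
  q_heat <- function(prefix, q, title) {
    cols <- paste0(prefix, ".q", q, ".i", seq_len(N))
    d <- tidyr::pivot_longer(trace[, c("time", cols)], -"time",
      names_to = "ch", values_to = "activity"
    )
    d$ch <- as.integer(sub(".*\\.i", "", d$ch))
    ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$ch, fill = pmax(.data$activity, 0))) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "white", high = "darkred", name = NULL) +
      ggplot2::labs(y = title, x = NULL) +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(legend.position = "none")
  }
  plan <- ggplot2::ggplot(trace) +
    ggplot2::geom_line(ggplot2::aes(.data$time, .data$x_PC.q1, colour = "feed")) +
    ggplot2::geom_line(ggplot2::aes(.data$time, .data$x_PC.q2, colour = "fear")) +
    ggplot2::scale_colour_manual(values = c(feed = "blue", fear = "red"), name = NULL) +
    ggplot2::labs(y = "plan cortex", x = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  stim <- tidyr::pivot_longer(
    trace[, c("time", paste0("S.i", seq_len(N)), "R.q1", "R.q2")], -"time",
    names_to = "input", values_to = "value"
  )
  drv <- ggplot2::ggplot(stim, ggplot2::aes(.data$time, .data$value, colour = .data$input)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(y = "S, R", x = "time (s)") +
    ggplot2::theme_minimal(base_size = 9)
  patchwork::wrap_plots(
    plan,
    q_heat("x_BA", 1, "BA+"), q_heat("x_BA", 2, "BA-"),
    .heat_panel(trace, "x_SC", seq_len(N), "cortex"),
    .heat_panel(trace, "x_SR", seq_len(N), "TRN"),
    .heat_panel(trace, "x_ST", seq_len(N), "thalamus"),
    drv,
    ncol = 1, heights = c(1.2, 1, 1, 1, 1, 1, 0.8)
  )
}

#' @export
autoplot.plan_timeline <- function(object, ...) {
  d <- object$timeline
  ggplot2::ggplot(d, ggplot2::aes(.data$time, 1, fill = .data$active)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(feed = "blue", fear = "red", none = "grey90"), name = NULL
    ) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Detection plot for a rubbernecking run
#'
#' Target-channel cortical activity around each trial with the per-trial
#' threshold overlaid; detected trials are marked.
#'
#' @param run Result of [run_rubbernecking()].
#' @return A ggplot.
#' @export
plot_detection <- function(run) {
  trials <- run$detection$trials
  d <- dplyr::mutate(trials, trial = factor(.data$trial))
  ggplot2::ggplot(d, ggplot2::aes(.data$trial)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$peak, fill = .data$detected)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$threshold), shape = 95, size = 6) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen", `FALSE` = "grey60")) +
    ggplot2::labs(
      x = "trial", y = "peak target cortical activity",
      title = sprintf(
        "lag %d steps: %.0f%% detected", run$lag_steps,
        100 * run$rate
      )
    ) +
    ggplot2::theme_minimal(base_size = 10)
}
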