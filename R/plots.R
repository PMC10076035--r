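#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a diffusion fit (log-log displacement vs time interval)
#'
#' @param object an `sfma_diffusion_fit`.
#' @param ... ignored.
#' @export
autoplot.sfma_diffusion_fit <- function(object, ...) {
  df <- object$displacement
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$dt),
                                   y = log(.data$mean_displacement))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$alpha, intercept = log(object$G),
                         linetype = 2) +
    ggplot2::labs(
      x = "log Δt", y = "log Δx",
      title = sprintf("α = %.3f, G = %.3f", object$alpha, object$G)
    )
}

#' Plot a reactivation map as a spatial heat map
#'
#' @param object an `sfma_reactivation_map`.
#' @param ... ignored.
#' @export
autoplot.sfma_reactivation_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = -.data$row,
                                       fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "fraction")
}

#' Plot a replay trace over the environment
#'
#' @param trace a trace tibble.
#' @param env the grid world.
#' @export
plot_trace <- function(trace, env) {
  df <- tibble::tibble(
    step = trace$step,
    row = env$coords[trace$s, 1],
    col = env$coords[trace$s, 2]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   color = .data$step)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, color = "step")
}

#' Plot escape-latency learning curves
#'
#' @param records a trial-record tibble (columns trial, latency, optionally a
#'   grouping column such as variant).
#' @param group optional name of a grouping column.
#' @export
plot_latency <- function(records, group = NULL) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$trial,
                                             y = .data$latency))
  if (!is.null(group)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(color = .data[[group]]))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "trial", y = "escape latency (steps)")
}
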