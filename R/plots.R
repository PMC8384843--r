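#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the channels of a simulation
#'
#' One facet per recorded channel over time.
#'
#' @param object A `wbp_simulation`.
#' @param channels Channels to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wbp_simulation <- function(object,
                                    channels = c("dps", "p_bulb", "t_bulb",
                                                 "q_aw", "v_bulb", "q_leak",
                                                 "t_chamber"),
                                    ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time",
                  dplyr::all_of(channels)),
    -"time", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an occlusion-release decay fit
#'
#' Shows the trace with the fitted exponential overlaid on the fitted
#' segment.
#'
#' @param object A `tau_fit` from [estimate_tau()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tau_fit <- function(object, ...) {
  d <- object$data
  seg <- d[object$segment, ]
  seg$fitted <- exp(stats::fitted(object$fit))
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line(data = seg,
                       ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time [s]", y = "pressure",
                  title = sprintf("tau = %.1f ms (fc = %.2f s⁻¹)",
                                  1000 * object$tau, object$fc)) +
    ggplot2::theme_minimal()
}

#' Plot flow, volume and breath landmarks of an analysed recording
#'
#' @param analysis A `wbp_analysis` from [analyze_breathing()].
#' @return A ggplot object with flow and volume facets; volume peaks are
#'   marked.
#' @export
plot_breaths <- function(analysis) {
  stopifnot(inherits(analysis, "wbp_analysis"))
  long <- dplyr::bind_rows(
    tibble::tibble(time = analysis$flow$time, value = analysis$flow$flow,
                   channel = "flow [mL/s]"),
    tibble::tibble(time = analysis$volume$time,
                   value = analysis$volume$volume, channel = "volume [mL]"))
  peaks <- tibble::tibble(time = analysis$breaths$t_peak,
                          value = analysis$breaths$v_t,
                          channel = "volume [mL]")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = peaks, colour = "red", size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}
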