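#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an encoding sweep
#'
#' Encoding transfer function (mean statistic versus stimulus, with
#' across-trial standard-deviation error bars) and, on request, the mean
#' encoding energy per level.
#'
#' @param object An [run_encoding_sweep()] result.
#' @param what `"statistic"` or `"energy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.encoding_sweep <- function(object, what = c("statistic", "energy"),
                                    ...) {
  what <- match.arg(what)
  ylab <- switch(object$mode[1],
    rate = "mean firing rate (Hz)",
    count = "mean spike count",
    timing = "mean first-spike timestep"
  )
  if (what == "statistic") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$stat_mean)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$stat_mean - .data$stat_sd,
                                          ymax = .data$stat_mean + .data$stat_sd),
                             width = 0.1) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "presynaptic voltage (V)", y = ylab) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$level,
                                         y = .data$energy_mean * 1e12)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "presynaptic voltage (V)", y = "encoding energy (pJ)") +
      ggplot2::theme_minimal()
  }
}

#' Raster plot of a spike train
#'
#' @param object A [spike_train()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_train <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_col(ggplot2::aes(y = as.numeric(.data$spike)), width =
                        object$t_p * 0.4) +
    ggplot2::labs(x = "time (s)", y = "spike") +
    ggplot2::theme_minimal()
}

#' Plot a correlation-coefficient trace
#'
#' @param object A [cc_trace()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cc_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$cc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "timestep", y = "correlation with original") +
    ggplot2::theme_minimal()
}

#' Plot the inference-error trace of a spiking network
#'
#' @param object An [snn_infer()] result run with labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snn_inference <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timestep, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "timesteps", y = "inference error") +
    ggplot2::theme_minimal()
}
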