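#' Heatmap of a stimulus kernel at one probe
#'
#' Time from saccade on the x-axis, response latency (delay) on the
#' y-axis.
#'
#' @param object a [kernel_field()].
#' @param probe linear probe id to display.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.kernel_field <- function(object, probe = 1, ...) {
  df <- as_tibble(object)
  df <- df[df$probe == probe, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$tau,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "time from saccade (ms)",
                  y = "delay from stimulus (ms)",
                  fill = "kernel",
                  title = sprintf("stimulus kernel, probe %d", probe)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a detectability map at one probe
#'
#' @param object a [detectability_map()].
#' @param probe linear probe id to display.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.detectability_map <- function(object, probe = NULL, ...) {
  if (is.null(probe)) probe <- object$probes[1]
  df <- as_tibble(object)
  df <- df[df$probe == probe, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$t,
                                   fill = .data$roc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "latency (ms)", y = "time from saccade (ms)",
                  fill = "ROC area",
                  title = sprintf("detectability, probe %d", probe)) +
    ggplot2::theme_minimal()
}

#' Prevalence map heatmap
#'
#' @param map percentage matrix from [prevalence_map()] (rows: time
#'   from saccade; columns: latency).
#' @param t_values,tau_values axis values; taken from `dimnames` when
#'   missing.
#' @return a ggplot.
#' @export
plot_prevalence <- function(map, t_values = NULL, tau_values = NULL) {
  if (is.null(t_values)) t_values <- as.numeric(rownames(map))
  if (is.null(tau_values)) tau_values <- as.numeric(colnames(map))
  df <- tibble::tibble(
    t = rep(t_values, times = ncol(map)),
    tau = rep(tau_values, each = nrow(map)),
    percent = as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$t,
                                   fill = .data$percent)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100)) +
    ggplot2::labs(x = "latency (ms)", y = "time from saccade (ms)",
                  fill = "% of neurons") +
    ggplot2::theme_minimal()
}

#' Maximum-detectability latency trace plot
#'
#' Latency of the detectability peak over time, marker size the peak
#' detectability, for the traced probes.
#'
#' @param trace tibble from [max_trace()].
#' @param valid_only drop invalid entries (default TRUE).
#' @return a ggplot.
#' @export
plot_max_trace <- function(trace, valid_only = TRUE) {
  if (valid_only) trace <- trace[trace$valid, , drop = FALSE]
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$t, y = .data$T,
                                      size = .data$I,
                                      colour = factor(.data$probe))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "time from saccade (ms)", y = "latency of peak (ms)",
                  size = "peak ROC", colour = "probe") +
    ggplot2::theme_minimal()
}
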