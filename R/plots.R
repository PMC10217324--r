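# ggplot2 displays for the three result types: per-bin net-change curves
# with their permutation bounds, a single tuning fit, and the lag decay of
# the fitted amplitude.

#' Plot a serial-dependence net-change curve
#'
#' Bars of the cost-direction net change per similarity bin, faceted by
#' metric, with the upper 95% permutation boundary as a dashed line and
#' significant bins (raw p < 0.05) highlighted.
#'
#' @param object A [serial_dependence()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot serial_dependence
#' @export
autoplot.serial_dependence <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!d$excluded, ]
  d$significant <- !is.na(d$p_value) & d$p_value < 0.05
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center, y = .data$cost)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), width = NULL) +
    ggplot2::geom_step(ggplot2::aes(y = .data$null_upper95),
                       linetype = "dashed", direction = "mid", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "n-back similarity (bin center)",
                  y = "net change, cost direction (past - future baseline)",
                  title = paste0("Serial dependence, lag ", unique(d$lag)[1])) +
    ggplot2::theme_minimal()
}

#' Plot a Gaussian tuning fit
#'
#' Observed cost-direction net change per bin with the fitted scaled
#' Gaussian overlaid; the peak (the serial-dependence amplitude) is marked.
#'
#' @param object A `tuning_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tuning_fit
#' @export
autoplot.tuning_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$bin_center), max(d$bin_center), length.out = 200)
  curve <- tibble::tibble(x = xs, y = gaussian_tuning(xs, object$a, object$mu, object$sigma))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center, y = .data$cost)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                       color = "#2980b9") +
    ggplot2::annotate("point", x = object$mu, y = object$peak,
                      shape = 4, size = 3, color = "#c0392b") +
    ggplot2::labs(x = "similarity (bin center)", y = "net change (cost direction)",
                  title = sprintf("%s, lag %s: peak %.3g",
                                  object$metric, object$lag, object$peak)) +
    ggplot2::theme_minimal()
}

#' Plot the temporal decay of serial-dependence amplitude
#'
#' Fitted peak amplitude versus lag, one line per metric, with null peak
#' bounds (when available) as open points.
#'
#' @param object An [amplitude_by_lag()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot amplitude_decay
#' @export
autoplot.amplitude_decay <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lag, y = .data$peak,
                                       color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag (n-back)", y = "serial-dependence amplitude (fitted peak)") +
    ggplot2::theme_minimal()
  if (any(!is.na(d$null_peak95))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$null_peak95),
                                 shape = 1, na.rm = TRUE)
  }
  p
}

#' @rdname autoplot.amplitude_decay
#' @export
plot_amplitude_decay <- function(object, ...) autoplot.amplitude_decay(object, ...)
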