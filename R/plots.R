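# ggplot2 visualisations for the main result types.

#' Bland-Altman plot
#'
#' @param object a `bland_altman` result.
#' @param ... unused.
#' @return ggplot object: paired differences vs. pair means with the bias
#'   and 1.96 SD limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  d <- attr(object, "differences")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_ga, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of estimated and reference GA (weeks)",
                  y = "Estimated - reference GA (weeks)",
                  title = sprintf("Bland-Altman: bias %.2f wk, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_lower, object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Quality-threshold sweep heat map
#'
#' @param object a `quality_sweep` tibble from [quality_threshold_sweep()].
#' @param ... unused.
#' @return ggplot object: MAE per threshold pair, excluded counts printed
#'   on the grid knots.
#' @export
autoplot.quality_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t_fecg, y = .data$t_dus)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mae)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_excluded), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = "fECG quality threshold", y = "DUS quality threshold",
                  fill = "LOO MAE (wk)",
                  title = "GA error vs. signal-quality gates (labels: n excluded)") +
    ggplot2::theme_minimal()
}

#' Plot a segment envelope with decoded events
#'
#' @param values z-normalised envelope segment.
#' @param fs sampling rate (Hz).
#' @param decoded optional tibble from [decode_events()] (columns
#'   `phase_ms`, `label`).
#' @return ggplot object.
#' @export
plot_segment <- function(values, fs, decoded = NULL) {
  df <- tibble::tibble(t_ms = (seq_along(values) - 1) / fs * 1000, env = values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$env)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time after R peak (ms)", y = "Envelope (z)") +
    ggplot2::theme_minimal()
  if (!is.null(decoded) && nrow(decoded)) {
    p <- p +
      ggplot2::geom_vline(data = decoded,
                          ggplot2::aes(xintercept = .data$phase_ms),
                          linetype = 3, colour = "grey50") +
      ggplot2::geom_text(data = decoded,
                         ggplot2::aes(x = .data$phase_ms, y = max(df$env),
                                      label = .data$label),
                         vjust = -0.3, size = 3)
  }
  p
}
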