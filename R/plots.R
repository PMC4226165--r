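#' Plot a heart-rate-variability spectrum
#'
#' Spectral density with the LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz)
#' bands shaded.
#'
#' @param object An `expl_spectrum` from [hrv_psd()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expl_spectrum <- function(object, ...) {
  bands <- tibble(band = c("LF", "HF"), xmin = c(0.04, 0.15),
                  xmax = c(0.15, 0.40))
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = 0,
                   ymax = Inf, fill = .data$band), alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(.data$frequency_hz, .data$psd)) +
    ggplot2::coord_cartesian(xlim = c(0, 0.5)) +
    ggplot2::labs(x = "frequency (Hz)", y = expression(PSD~(ms^2/Hz)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Correlation-matrix heatmap
#'
#' @param object An `expl_cormat` from [pearson_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expl_cormat <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$r,
                      ifelse(.data$p < 0.01, "**",
                             ifelse(.data$p < 0.05, "*", "")))),
      size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Scatter of entropy against an autonomic change score
#'
#' The package's headline relationship: per-subject exploration (entropy)
#' against a task-minus-baseline autonomic change score, with the least
#' squares line and the Pearson r in the subtitle.
#'
#' @param data A data frame with one row per subject containing `entropy`
#'   and the chosen change-score column (e.g. the `data` element of a
#'   [run_full()] condition result).
#' @param variable Change-score column to plot (default
#'   `"norepinephrine"`).
#' @return A ggplot.
#' @export
plot_entropy_coupling <- function(data, variable = "norepinephrine") {
  stopifnot(is.data.frame(data), variable %in% names(data),
            "entropy" %in% names(data))
  r <- cor(data[[variable]], data$entropy)
  ggplot2::ggplot(data, ggplot2::aes(.data[[variable]], .data$entropy)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#B2182B") +
    ggplot2::labs(x = sprintf("Δ %s (task - baseline)", variable),
                  y = "entropy (normalized bits)",
                  subtitle = sprintf("Pearson r = %.2f (n = %d)", r,
                                     nrow(data))) +
    ggplot2::theme_minimal()
}

#' Per-condition behavioral index summary plot
#'
#' Block-level distributions of response bias, reward acquisition and
#' entropy by condition.
#'
#' @param indices Output of [score_trials()].
#' @return A ggplot.
#' @export
plot_behavioral_indices <- function(indices) {
  stopifnot(is.data.frame(indices))
  d <- indices %>%
    tidyr::pivot_longer(c("response_bias", "reward_acquisition", "entropy"),
                        names_to = "index")
  ggplot2::ggplot(d, ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
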