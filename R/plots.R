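#' Plot a dF/F trace with optional detected events
#'
#' @param dff A `gliatrace_dff` tibble.
#' @param events Optional `gliatrace_events` tibble; event spans are
#'   shaded and peaks marked.
#' @return A ggplot object.
#' @export
plot_dff <- function(dff, events = NULL) {
  p <- ggplot2::ggplot(dff, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p +
      ggplot2::geom_rect(
        data = tibble::as_tibble(events),
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "#fec44f", alpha = 0.3
      ) +
      ggplot2::geom_point(
        data = tibble::as_tibble(events),
        ggplot2::aes(x = .data$peak_time_s,
                     y = .data$amplitude + attr(events, "baseline_mean")),
        inherit.aes = FALSE, colour = "#d95f0e"
      )
  }
  p
}

#' Heat map of fold changes from a region screen
#'
#' One tile per region and pairwise comparison, filled by log2 fold
#' change, with significant comparisons (q below the screen's FDR level)
#' starred.
#'
#' @param object A `gliatrace_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gliatrace_screen <- function(object, ...) {
  d <- tidy(object)
  d$log2_fc <- log2(d$fold_change)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$comparison,
                                  y = factor(.data$region_id),
                                  fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(data = d[d$significant, , drop = FALSE], label = "*",
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", na.value = "grey80") +
    ggplot2::labs(x = "comparison", y = "region",
                  fill = "log2 fold change") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot for an ensemble correlation
#'
#' @param regions The tibble passed to [engram_correlation()] (with
#'   `delta_a`, `delta_b` and flag columns).
#' @param result The fitted `gliatrace_cor` object.
#' @return A ggplot object showing kept regions with the Pearson r in the
#'   subtitle.
#' @export
plot_engram_correlation <- function(regions, result) {
  kept <- result$selection_log$kept
  d <- regions[kept, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_a, y = .data$delta_b)) +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(
      x = "neuronal Fos+ count change", y = "astrocytic Fos+ count change",
      subtitle = sprintf("Pearson r = %.2f (n = %d regions)",
                         result$r, result$n_regions)
    ) +
    ggplot2::theme_minimal()
}

#' Box plot of the co-expression index per condition
#'
#' @param ci Output of [coexpression_index()].
#' @return A ggplot object (log-scaled y axis).
#' @export
plot_coexpression <- function(ci) {
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$condition,
                                   y = .data$coexpression_index)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "#c7e9b4") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "condition", y = "co-expression index") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
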