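#' Plot index score distributions by wave
#'
#' Faceted histograms of harmonized index scores per wave — the visual
#' clumping/truncation check.
#'
#' @param object A `harmonized_index`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot harmonized_index
#' @export
autoplot.harmonized_index <- function(object, bins = 40, ...) {
  df <- object$scores
  df$wave <- factor(df$wave, levels = object$waves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~wave, scales = "free_y") +
    ggplot2::labs(x = "harmonized index score", y = "households") +
    ggplot2::theme_minimal()
}

#' Plot item loadings of a fitted index model
#'
#' @param object An `index_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot index_model
#' @export
autoplot.index_model <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$item, levels = df$item[order(df$loading)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$item)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "loading on first component", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity report
#'
#' Spearman correlations with the benchmark per variant, grouped by block.
#'
#' @param report A `sensitivity_report`.
#' @return A ggplot.
#' @export
plot_sensitivity <- function(report) {
  df <- report[report$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$spearman)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = sensitivity_summary(df),
                        ggplot2::aes(y = .data$min_spearman),
                        colour = "red", shape = 4, size = 2.5) +
    ggplot2::labs(x = NULL, y = "Spearman r vs benchmark") +
    ggplot2::theme_minimal()
}
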