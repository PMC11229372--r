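# ggplot2 visualisations for the main result types.

#' Plot a colocalization test result
#'
#' Shows each protein pair's BH-adjusted significance (-log10 scale)
#' against its observed shared fraction.
#'
#' @param object A `coloc_test` object.
#' @param alpha Significance level drawn as a reference line (default
#'   0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coloc_test <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$pair <- paste(df$protein1, df$protein2, sep = " / ")
  # the smallest resolvable p at n draws keeps p = 0 plottable
  floor_p <- 1 / (attr(object, "n_samples") %||% 5000L)
  df$neglog_p <- -log10(pmax(df$p_adj, floor_p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fo, y = .data$neglog_p)) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$pair), hjust = -0.05,
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "observed shared fraction (Fo)",
                  y = expression(-log[10] ~ "BH-adjusted p"),
                  title = "Promoter colocalization") +
    ggplot2::theme_minimal()
}

#' Plot the peak distribution summary
#'
#' Bar chart of peak counts by genomic feature, faceted by chromatin
#' compartment, filled by motif status.
#'
#' @param distribution Output of [summarize_peak_distribution()].
#' @return A ggplot object.
#' @export
plot_peak_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = .data$feature, y = .data$n,
                               fill = .data$has_motif)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = NULL, y = "peaks", fill = "motif") +
    ggplot2::theme_minimal()
}

#' Plot label-combination counts
#'
#' UpSet-style bar chart of merged-region counts per set combination.
#'
#' @param combos Output of [combination_counts()].
#' @return A ggplot object.
#' @export
plot_combination_counts <- function(combos) {
  combos$combination <- factor(combos$combination,
                               levels = rev(combos$combination))
  ggplot2::ggplot(combos, ggplot2::aes(x = .data$n, y = .data$combination)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "regions", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
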