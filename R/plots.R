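#' Bar chart of category fractions
#'
#' @param x An `rna_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_category_fractions <- function(x, ...) {
  fr <- category_fractions(x)
  fr$category <- factor(fr$category, levels = fr$category)
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of processed reads",
                  title = sprintf("Strategy %d", x$strategy)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_category_fractions
#' @importFrom ggplot2 autoplot
#' @export
autoplot.rna_classification <- function(x, ...) {
  plot_category_fractions(x, ...)
}

#' Phylum-style rollup bar chart (log10 counts, solid vs masked bars)
#'
#' Mirrors the field's standard presentation: one bar per taxon with the
#' read count on a log10 axis, and, when a masked rollup is supplied,
#' open bars showing counts after rRNA/tRNA removal next to the solid
#' unmasked bars. Taxa with zero counts are dropped, not drawn at -Inf.
#'
#' @param unmasked Tibble from [rollup_mean()] (all assignments).
#' @param masked Optional tibble from [rollup_mean()] after
#'   [mask_structural_rna()].
#' @return A ggplot object.
#' @export
plot_rollup <- function(unmasked, masked = NULL) {
  u <- rollup_plot_data(unmasked)
  u$set <- "all reads"
  d <- u
  if (!is.null(masked)) {
    m <- rollup_plot_data(masked)
    m$set <- "rRNA/tRNA removed"
    d <- dplyr::bind_rows(u, m)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$name, y = .data$log10_count,
                                  fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      colour = "grey20") +
    ggplot2::scale_fill_manual(values = c("all reads" = "grey25",
                                          "rRNA/tRNA removed" = "white")) +
    ggplot2::labs(x = NULL, y = "log10(mean reads)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Strategy-sweep bar chart
#'
#' @param tbl Output of [strategy_table()].
#' @return A ggplot object.
#' @export
plot_strategy_table <- function(tbl) {
  long <- tidyr::pivot_longer(tbl, dplyr::starts_with("strategy_"),
                              names_to = "strategy", names_prefix = "strategy_",
                              values_to = "percent")
  long$category <- factor(long$category, levels = tbl$category)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy, y = .data$percent,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mismatch strategy", y = "% of processed reads",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
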