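# ggplot2 displays for census results.

#' Plot domain length against cysteine count by architecture
#'
#' The classic two-cluster view of a TLP family: typical domains (~215 aa,
#' 16 Cys) versus small domains (~150 aa, 10 Cys), kinase fusions marked by
#' shape.
#'
#' @param x A `tlp_census` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tlp_census <- function(x, ...) {
  df <- x$classification |> filter(!is.na(.data$domain_len))
  ggplot2::ggplot(df, ggplot2::aes(.data$domain_len, .data$n_cys,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "Thaumatin domain length (aa)",
                  y = "Cysteines in domain", colour = "Architecture") +
    ggplot2::theme_minimal()
}

#' Bar plot of transposable-element coverage fractions
#'
#' @param coverage A `te_coverage` object.
#' @return A ggplot object.
#' @export
plot_te_coverage <- function(coverage) {
  df <- tidy(coverage)
  ggplot2::ggplot(df, ggplot2::aes(.data$te_class, .data$fraction)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "Coverage of region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-column conservation profile of an alignment
#'
#' Displays the four-level conservation code from [column_conservation()]
#' (1 = invariant, 4 = highly variable) along the alignment.
#'
#' @param alignment Alignment tibble (`id`, `sequence`).
#' @return A ggplot object.
#' @export
plot_conservation <- function(alignment) {
  lev <- column_conservation(alignment)
  df <- tibble(column = seq_along(lev), level = lev)
  ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$level)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::scale_y_reverse(breaks = 1:4) +
    ggplot2::labs(x = "Alignment column",
                  y = "Conservation level (1 = invariant)") +
    ggplot2::theme_minimal()
}
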