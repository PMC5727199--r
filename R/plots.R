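#' Plot a per-variant oncogenicity summary
#'
#' Bar plot of wild-type-relative normalized tumor numbers with bootstrap
#' confidence intervals; variants significantly enriched over WT are
#' colored.
#'
#' @param object A `variant_summary` (see [variant_summary()]).
#' @param alpha Significance threshold on the corrected p-value vs WT.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variant_summary
#' @export
autoplot.variant_summary <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$enriched <- !is.na(df$p_vs_wt) & df$p_vs_wt < alpha
  df$variant <- stats::reorder(df$variant, -df$relative)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$relative,
                                   fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "steelblue"),
                               name = "enriched vs WT") +
    ggplot2::labs(x = NULL, y = "relative tumor number (WT = 1)") +
    ggplot2::theme_minimal()
}

#' Plot tumor size distributions per variant
#'
#' @param calls Call tibble with `variant` and `cells`.
#' @return A ggplot object (log10 cell numbers).
#' @export
plot_size_distribution <- function(calls) {
  df <- calls[!is.na(calls$cells) & calls$cells > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$cells)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "neoplastic cells (log scale)") +
    ggplot2::theme_minimal()
}

#' Plot a clone map across samples
#'
#' Dots are clones within each sample (diameter proportional to the square
#' root of within-sample relative size); lines connect calls sharing a
#' variant-barcode pair, dashed for metastatic links.
#'
#' @param object A `clone_map` (see [match_clones()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clone_map
#' @export
autoplot.clone_map <- function(object, ...) {
  nodes <- object$nodes
  nodes$y <- as.integer(factor(paste(nodes$variant, nodes$barcode)))
  edges <- object$edges
  if (nrow(edges) > 0) {
    key <- paste(nodes$sample, nodes$variant, nodes$barcode)
    edges$x_a <- match(edges$sample_a, levels(factor(nodes$sample)))
    edges$x_b <- match(edges$sample_b, levels(factor(nodes$sample)))
    edges$y <- nodes$y[match(paste(edges$sample_a, edges$variant,
                                   edges$barcode), key)]
  }
  p <- ggplot2::ggplot(nodes,
                       ggplot2::aes(x = factor(.data$sample), y = .data$y))
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_a, xend = .data$x_b,
                   y = .data$y, yend = .data$y,
                   linetype = .data$type),
      inherit.aes = FALSE, color = "grey40"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$diameter,
                                     color = .data$variant,
                                     shape = .data$role)) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_shape_manual(values = c(primary = 16, metastasis = 17)) +
    ggplot2::labs(x = NULL, y = "clone") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
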