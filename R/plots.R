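#' ENc plot against GC3s with the expected curve
#'
#' Scatter of observed ENc against GC3s with the GC3s-only expectation
#' `2 + gc3s + 29/(gc3s^2 + (1-gc3s)^2)` overlaid. Genes lying on the curve
#' are compatible with purely compositional (mutational) bias; genes well
#' below it are shaped by additional selection.
#'
#' @param indices A [codon_usage_indices()] table.
#' @return A ggplot object.
#' @export
plot_enc_gc3s <- function(indices) {
  curve_df <- tibble::tibble(gc3s = seq(0, 1, length.out = 201))
  curve_df$enc <- enc_expected(curve_df$gc3s)
  ggplot2::ggplot(indices, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, na.rm = TRUE) +
    ggplot2::geom_line(data = curve_df, colour = "red") +
    ggplot2::labs(x = "GC3s", y = "ENc") +
    ggplot2::coord_cartesian(ylim = c(20, 61)) +
    ggplot2::theme_minimal()
}

#' PR2 plot
#'
#' A3/(A3+T3) against G3/(G3+C3) at the configured third-position scope, with
#' the (0.5, 0.5) no-asymmetry centre marked.
#'
#' @param indices A table with `pr2_x`, `pr2_y` columns.
#' @return A ggplot object.
#' @export
plot_pr2 <- function(indices) {
  ggplot2::ggplot(indices, ggplot2::aes(x = .data$pr2_x, y = .data$pr2_y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Histogram of relative ENc deviation
#'
#' Distribution of `(ENc_exp - ENc_obs)/ENc_exp` in bins of width 0.1.
#'
#' @param indices A [codon_usage_indices()] table.
#' @param binwidth Bin width.
#' @return A ggplot object.
#' @export
plot_enc_deviation <- function(indices, binwidth = 0.1) {
  ggplot2::ggplot(indices, ggplot2::aes(x = .data$enc_deviation)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white", na.rm = TRUE) +
    ggplot2::labs(x = "(ENc exp - ENc obs) / ENc exp", y = "genes") +
    ggplot2::theme_minimal()
}

#' RSCU bar chart
#'
#' @param rscu_tbl A [rscu()] table.
#' @return A ggplot object.
#' @export
plot_rscu <- function(rscu_tbl) {
  ggplot2::ggplot(rscu_tbl,
                  ggplot2::aes(x = .data$codon, y = .data$rscu, fill = .data$aa)) +
    ggplot2::geom_col(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::facet_grid(~aa, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                   strip.text = ggplot2::element_text(size = 6))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination plot of a correspondence analysis
#'
#' Genes on Axis1/Axis2, optionally coloured by GC class when an index table
#' is supplied.
#'
#' @param object A `codon_coa` object.
#' @param indices Optional [codon_usage_indices()] table for GC colouring.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.codon_coa <- function(object, indices = NULL, ...) {
  df <- object$gene_coords
  frac <- object$inertia$fraction
  lab <- function(i) sprintf("Axis%d (%.1f%%)", i, 100 * frac[i])
  if (!is.null(indices) && "gc" %in% names(indices)) {
    df <- dplyr::inner_join(df, indices[, c("gene_id", "gc")], by = "gene_id")
    df$gc_class <- gc_class(df$gc)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2,
                                          colour = .data$gc_class)) +
      ggplot2::scale_colour_manual(
        values = c(low = "darkgreen", mid = "goldenrod", high = "brown"),
        name = "GC class"
      )
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2))
  }
  p + ggplot2::geom_point(alpha = 0.5, size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a correlation table
#'
#' Tile plot of a `codon_corr` long correlation table with significance
#' stars (* p < 0.05, ** p < 0.01).
#'
#' @param object A `codon_corr` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.codon_corr <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$stars <- ifelse(df$sig_01, "**", ifelse(df$sig_05, "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(.data$var2, .data$var1, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Score plot of a species RSCU PCA
#'
#' @param object A `codon_pca` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.codon_pca <- function(object, ...) {
  df <- object$scores
  expl <- object$explained
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1,
                                   if ("PC2" %in% names(df)) .data$PC2 else 0)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$species),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * expl[1]),
      y = if (length(expl) > 1) sprintf("PC2 (%.1f%%)", 100 * expl[2]) else "PC2"
    ) +
    ggplot2::theme_minimal()
}
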