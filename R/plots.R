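# ggplot2 displays for the main result types.

#' Plot per-codon occupancy traces for one gene
#'
#' @param occupancy Output of [normalize_occupancy()].
#' @param gene Gene id to display.
#' @param samples Optional sample subset.
#' @return A ggplot: occupancy along CDS codons, one panel per sample.
#' @export
plot_occupancy_trace <- function(occupancy, gene, samples = NULL) {
  df <- occupancy[occupancy$gene_id == gene & occupancy$codon >= 1, ]
  if (!is.null(samples)) df <- df[df$sample_id %in% samples, ]
  if (nrow(df) == 0) abort("no occupancy rows for that gene/sample selection")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$occupancy)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sample_id, ncol = 1) +
    ggplot2::labs(x = "CDS codon", y = "normalized occupancy", title = gene) +
    ggplot2::theme_minimal()
}

#' Distribution of per-transcript trace correlations
#'
#' @param correlations Output of [correlate_all()], optionally with a
#'   `condition_pair` column distinguishing comparisons (e.g. log phase vs
#'   quiescence).
#' @return A ggplot density/violin of uncentered correlations.
#' @export
plot_trace_correlations <- function(correlations) {
  if (!"condition_pair" %in% names(correlations)) {
    correlations$condition_pair <- "euploid vs aneuploid"
  }
  ggplot2::ggplot(correlations,
                  ggplot2::aes(x = .data$condition_pair, y = .data$correlation)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "uncentered Pearson correlation") +
    ggplot2::theme_minimal()
}

#' Relative positions of differential pause sites by direction
#'
#' @param x A `ribo_peaks_combined` object.
#' @param ... Unused.
#' @return A ggplot comparing relative peak positions between directions.
#' @export
autoplot.ribo_peaks_combined <- function(x, ...) {
  ggplot2::ggplot(x$sites,
                  ggplot2::aes(x = .data$direction, y = .data$relative_position,
                               fill = .data$direction)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(aneuploid_higher = "#E69F00",
                                          euploid_higher = "#7B68AE")) +
    ggplot2::labs(x = NULL, y = "relative position on transcript") +
    ggplot2::theme_minimal()
}

#' Heatmap of flanking-residue enrichment around pause sites
#'
#' Displays the log2 enrichment of each residue at each position relative
#' to the P site, masking cells that do not reach the FDR threshold (the
#' standard stall-motif display).
#'
#' @param enrichment Output of [position_enrichment()].
#' @param significant_only Mask non-significant cells (default `TRUE`).
#' @return A ggplot tile heatmap (position x residue).
#' @export
plot_motif_enrichment <- function(enrichment, significant_only = TRUE) {
  df <- enrichment
  df$shown <- ifelse(significant_only & !df$significant, NA_real_,
                     df$log2_enrichment)
  df$shown[is.infinite(df$shown)] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = factor(.data$symbol, rev(AA_ALPHABET_21)),
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", na.value = "grey92",
                                  name = "log2 enrichment") +
    ggplot2::labs(x = "position relative to P site (0 = P, +1 = A)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
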