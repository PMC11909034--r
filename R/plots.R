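#' Plot a clustered sample-correlation heatmap
#'
#' @param object A `correlation_heatmap`.
#' @param ... Unused.
#' @return A ggplot: samples in clustered order, tiles coloured by Pearson
#'   r.
#' @export
autoplot.correlation_heatmap <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Volcano plot of a DEP contrast
#'
#' @param table A DEP table from [call_deps()].
#' @param contrast Contrast name to plot (default: first).
#' @return A ggplot of log2FC vs -log10 FDR with DEPs highlighted.
#' @export
plot_volcano <- function(table, contrast = NULL) {
  contrast <- contrast %||% table$contrast[1]
  df <- dplyr::filter(table, .data$contrast == !!contrast)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$is_dep)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B")) +
    ggplot2::labs(title = contrast, x = "log2 fold change",
                  y = "-log10 FDR", colour = "DEP") +
    ggplot2::theme_minimal()
}

#' Rank-intensity plot with platform-overlap highlighting
#'
#' @param rank_table Output of [rank_intensity()].
#' @return A ggplot of mean intensity vs abundance rank, highlighted
#'   proteins coloured.
#' @export
plot_rank_intensity <- function(rank_table) {
  ggplot2::ggplot(rank_table, ggplot2::aes(.data$rank, .data$mean_intensity,
                                           colour = .data$highlighted)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2166AC"),
                                 labels = c("platform-unique", "shared")) +
    ggplot2::labs(x = "Abundance rank", y = "Mean intensity (vst)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Rank trajectories of the most abundant proteins over time
#'
#' @param top_ranks Output of [top_rank_trajectory()].
#' @return A bump-chart ggplot (rank vs timepoint, one line per protein).
#' @export
plot_top_ranks <- function(top_ranks) {
  ggplot2::ggplot(top_ranks, ggplot2::aes(.data$timepoint_months, .data$rank,
                                          colour = .data$protein_id)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_reverse(breaks = sort(unique(top_ranks$rank))) +
    ggplot2::labs(x = "Months", y = "Abundance rank", colour = "Protein") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-patient direction consistency
#'
#' @param consistency Output of [consistency_scores()].
#' @return A ggplot tile map (protein x timepoint, fill = fraction of
#'   patients changing in the reference direction).
#' @export
plot_consistency <- function(consistency) {
  ggplot2::ggplot(consistency,
                  ggplot2::aes(factor(.data$timepoint_months), .data$protein_id,
                               fill = .data$consistency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = NULL, fill = "Consistency") +
    ggplot2::theme_minimal()
}

#' Change-change volcano of the protein screen
#'
#' @param screen Output of [clinical_correlation()].
#' @param highlight Feature IDs to flag (e.g. proteins significant on the
#'   other platform).
#' @return A ggplot of Pearson r vs -log10 p per protein.
#' @export
plot_screen <- function(screen, highlight = character()) {
  df <- dplyr::mutate(screen, highlighted = .data$feature %in% highlight)
  ggplot2::ggplot(df, ggplot2::aes(.data$r, -log10(pmax(.data$p, 1e-300)),
                                   colour = .data$highlighted)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "Pearson r (delta protein vs delta HFMSE)",
                  y = "-log10 p", colour = "Highlighted") +
    ggplot2::theme_minimal()
}
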