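#' Volcano plot of a differential-expression table
#'
#' @param de An `llr_de` tibble.
#' @param lfc_threshold,fdr_threshold Thresholds drawn as guide lines and
#'   used to color significant genes.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_threshold = 1, fdr_threshold = 0.01) {
  de <- classify_de(de, lfc_threshold, fdr_threshold)
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$fdr, 1e-300)),
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#d95f02", down = "#1b9e77",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL, title = de$contrast[1]) +
    ggplot2::theme_minimal()
}

#' Divergence trajectories of passing genes
#'
#' AO-NM log2 fold change across the regeneration time course for genes
#' passing the divergence filter, colored by direction, with per-direction
#' mean trajectories overlaid.
#'
#' @param calls An `llr_divergence` tibble from [divergence_filter()].
#' @return A ggplot object.
#' @export
plot_divergence_trajectories <- function(calls) {
  passing <- calls[calls$passes, , drop = FALSE]
  long <- tidyr::pivot_longer(
    passing[c("gene", "direction", "lfc_12h", "lfc_24h", "lfc_ut")],
    cols = dplyr::starts_with("lfc_"), names_to = "timepoint",
    names_prefix = "lfc_", values_to = "log2fc")
  long$timepoint <- factor(long$timepoint, levels = c("12h", "24h", "ut"),
                           labels = c("12 hpt", "24 hpt", "untreated"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$log2fc,
                                     group = .data$gene,
                                     colour = .data$direction)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$direction),
                          fun = mean, geom = "line", linewidth = 1.2) +
    ggplot2::scale_colour_manual(values = c(AO_high = "#e6ab02",
                                            NM_high = "#386cb0")) +
    ggplot2::labs(x = NULL, y = "AO - NM log2 fold change", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_volcano autoplot method for `llr_de`.
#' @param object,... passed through.
#' @exportS3Method ggplot2::autoplot
autoplot.llr_de <- function(object, ...) plot_volcano(object, ...)

#' Plot a co-expression network
#'
#' Fruchterman-Reingold layout with node size proportional to the sum of
#' absolute incident correlations (the node-weight convention used for
#' network figures).
#'
#' @param object An `llr_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.llr_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$gene)
  edges <- dplyr::mutate(object$edges,
                         x = nodes$x[pos[.data$from]],
                         y = nodes$y[pos[.data$from]],
                         xend = nodes$x[pos[.data$to]],
                         yend = nodes$y[pos[.data$to]])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey80", linewidth = 0.3)
  if ("group" %in% names(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 size = .data$weight, colour = .data$group))
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y,
                                 size = .data$weight))
  }
  p + ggplot2::scale_size_area(max_size = 8) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "sum |r|", colour = NULL)
}

#' GSEA running-sum plot
#'
#' @param object An `llr_gsea` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.llr_gsea <- function(object, ...) {
  rs <- object$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#386cb0") +
    ggplot2::geom_rug(data = rs[rs$hit, ], sides = "b", colour = "grey30") +
    ggplot2::labs(x = "rank", y = "running enrichment score",
                  title = paste0("ES = ", format(object$es, digits = 3))) +
    ggplot2::theme_minimal()
}
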