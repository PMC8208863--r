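#' Volcano plot of a differential screen
#'
#' Signed fold change (log2 of the linear magnitude, sign kept) against
#' -log10 p, with the screen's gates drawn as reference lines.
#'
#' @param object A [screen_de()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cerna_screen <- function(object, ...) {
  df <- as_tibble(object)
  df$signed_log2_fc <- sign(df$fold_change) * log2(abs(df$fold_change))
  fc_cut <- attr(object, "fc_cut") %||% 2
  p_cut <- attr(object, "p_cut") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(.data$signed_log2_fc,
                                   -log10(.data$p_value),
                                   colour = .data$passes,
                                   shape = .data$type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_cut),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(p_cut),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey65",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "signed log2 fold change", y = "-log10 p",
                  colour = "passes", shape = "class") +
    ggplot2::theme_minimal()
}

#' Dot plot of enrichment results
#'
#' The conventional over-representation dot plot: enrichment factor on x,
#' terms on y ordered by significance, point size = overlap count, colour =
#' -log10 p, faceted by category.
#'
#' @param object A [enrich()] result.
#' @param top_n Terms shown per category.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cerna_enrichment <- function(object, top_n = 30, ...) {
  df <- as_tibble(object) |>
    group_by(.data$category) |>
    slice_head(n = top_n) |>
    ungroup()
  df$term <- stats::reorder(paste(df$term_id, df$name), -df$p_value)
  ggplot2::ggplot(df, ggplot2::aes(.data$enrichment_factor, .data$term,
                                   size = .data$k,
                                   colour = -log10(.data$p_value))) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::scale_colour_gradient(low = "darkgreen", high = "red") +
    ggplot2::labs(x = "enrichment factor", y = NULL, size = "genes",
                  colour = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Plot a ceRNA graph
#'
#' Force-directed layout with the conventional ceRNA glyphs: squares for
#' lncRNAs, circles for miRNAs, diamonds for mRNAs.
#'
#' @param object A `cerna_graph`.
#' @param seed Layout seed (layouts are stochastic).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cerna_graph <- function(object, seed = 1, ...) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(object)
  nodes <- tibble(x = xy[, 1], y = xy[, 2],
                  name = igraph::V(object)$name,
                  type = igraph::vertex_attr(object, "type"))
  el <- igraph::as_edgelist(object)
  pos <- setNames(seq_len(nrow(nodes)), nodes$name)
  edges <- tibble(x = nodes$x[pos[el[, 1]]], y = nodes$y[pos[el[, 1]]],
                  xend = nodes$x[pos[el[, 2]]], yend = nodes$y[pos[el[, 2]]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(.data$x, .data$y, xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, shape = .data$type,
                                     colour = .data$type), size = 2) +
    ggplot2::scale_shape_manual(values = c(lnc = 15, mi = 16, m = 18)) +
    ggplot2::theme_void() +
    ggplot2::labs(shape = "class", colour = "class")
}
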