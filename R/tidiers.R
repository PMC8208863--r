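#' Tidy a ceRNA graph into its node table
#'
#' @param x A `cerna_graph`.
#' @param ... Unused.
#' @return The [node_degrees()] tibble.
#' @export
tidy.cerna_graph <- function(x, ...) node_degrees(x)

#' One-row summary of a ceRNA graph
#'
#' @param x A `cerna_graph`.
#' @param ... Unused.
#' @return Tibble with `n_lnc`, `n_mi`, `n_m`, `n_nodes`, `n_edges`,
#'   `n_lnc_mi_edges`, `n_mi_m_edges`.
#' @export
glance.cerna_graph <- function(x, ...) {
  types <- igraph::vertex_attr(x, "type")
  et <- igraph::edge_attr(x, "edge_type")
  tibble(n_lnc = sum(types == "lnc"),
         n_mi = sum(types == "mi"),
         n_m = sum(types == "m"),
         n_nodes = igraph::vcount(x),
         n_edges = igraph::ecount(x),
         n_lnc_mi_edges = sum(et == "lnc-mi"),
         n_mi_m_edges = sum(et == "mi-m"))
}

#' One-row summary of a differential screen
#'
#' @param x A `cerna_screen` tibble.
#' @param ... Unused.
#' @return Tibble with per-class passing counts (`n_dels`, `n_demis`,
#'   `n_dems`), total tested, and the gates used.
#' @export
glance.cerna_screen <- function(x, ...) {
  part <- de_partition(x)
  tibble(n_dels = length(part$dels),
         n_demis = length(part$demis),
         n_dems = length(part$dems),
         n_tested = nrow(x),
         p_cut = attr(x, "p_cut"),
         fc_cut = attr(x, "fc_cut"))
}

#' Per-category summary of an enrichment result
#'
#' @param x A `cerna_enrichment` tibble.
#' @param ... Unused.
#' @return The per-category enriched-term totals (terms with raw p below the
#'   cut used in [enrich()]).
#' @export
glance.cerna_enrichment <- function(x, ...) {
  totals <- attr(x, "category_totals")
  if (is.null(totals)) {
    totals <- x |>
      group_by(.data$category) |>
      summarise(n_enriched = sum(.data$p_value < 0.05), .groups = "drop")
  }
  totals
}
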