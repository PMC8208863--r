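#' Node degree table of a ceRNA graph
#'
#' @param graph A [build_graph()] result.
#' @return Tibble: `node_id`, `degree`, `type`, `fold_change`, sorted by
#'   descending degree then id.
#' @export
node_degrees <- function(graph) {
  deg <- igraph::degree(graph)
  out <- tibble(node_id = names(deg),
                degree = as.integer(unname(deg)),
                type = igraph::vertex_attr(graph, "type"),
                fold_change = igraph::vertex_attr(graph, "fold_change"))
  arrange(out, desc(.data$degree), .data$node_id)
}

#' Hub nodes of a ceRNA network
#'
#' Selects nodes whose degree meets the hub threshold. Although the usual
#' phrasing is a degree "exceeding" the threshold, published hub tables for
#' this pipeline include threshold-degree nodes, so the gate is `degree >=
#' threshold`; set `threshold = 6` for the strict reading.
#'
#' @param degrees A degree table — either [node_degrees()] output or any data
#'   frame with columns `node_id`, `degree`, `type` (and optionally
#'   `fold_change`). A `cerna_graph` is also accepted and converted.
#' @param threshold Minimum hub degree (default 5).
#' @return Tibble of hub rows sorted by descending degree then id, with
#'   per-type hub counts attached as attribute `"type_counts"`.
#' @export
hub_nodes <- function(degrees, threshold = 5) {
  if (inherits(degrees, "cerna_graph")) degrees <- node_degrees(degrees)
  degrees <- as_tibble(degrees)
  need <- c("node_id", "degree", "type")
  if (!all(need %in% names(degrees))) {
    abort("`degrees` needs columns node_id, degree, type")
  }
  hubs <- degrees[degrees$degree >= threshold, ]
  hubs <- arrange(hubs, desc(.data$degree), .data$node_id)
  counts <- table(factor(hubs$type, levels = c("lnc", "mi", "m")))
  attr(hubs, "type_counts") <- as.integer(counts) |>
    setNames(names(counts))
  hubs
}

#' First/second relationship-pair counts per lncRNA
#'
#' For each lncRNA L in the graph: `n_first` is the number of lncRNA-miRNA
#' edges incident to L (its degree); `n_second` is the number of miRNA-mRNA
#' edges incident to L's miRNA partners, counting each such edge once per
#' incident partner miRNA; `total = n_first + n_second`. `total` equals the
#' edge count of [extract_subnetwork()] for L.
#'
#' @param graph A [build_graph()] result.
#' @return Tibble: `lnc_id`, `n_first`, `n_second`, `total`, sorted by
#'   descending `n_first` then `total` then id.
#' @export
pair_counts <- function(graph) {
  types <- igraph::vertex_attr(graph, "type")
  names(types) <- igraph::V(graph)$name
  lncs <- names(types)[types == "lnc"]
  rows <- lapply(lncs, function(L) {
    mis <- igraph::neighbors(graph, L)$name
    mis <- mis[types[mis] == "mi"]
    n_second <- sum(vapply(mis, function(u) {
      nb <- igraph::neighbors(graph, u)$name
      sum(types[nb] == "m")
    }, numeric(1)))
    tibble(lnc_id = L, n_first = length(mis),
           n_second = as.integer(n_second))
  })
  out <- if (length(rows)) bind_rows(rows) else
    tibble(lnc_id = character(), n_first = integer(), n_second = integer())
  out$total <- out$n_first + out$n_second
  arrange(out, desc(.data$n_first), desc(.data$total), .data$lnc_id)
}

#' Rank key lncRNAs by relationship-pair counts
#'
#' Orders lncRNAs by number of miRNA partners (`n_first`, descending), then
#' total relationship pairs (`total`, descending), then id (ascending, the
#' deterministic tie-break), and returns the top `k`.
#'
#' @param pair_tbl Pair-count table — [pair_counts()] output or any data
#'   frame with columns `lnc_id`, `n_first`, `n_second` and/or `total`.
#' @param hubs Optional hub table ([hub_nodes()]); when given, ranking is
#'   restricted to hub lncRNAs.
#' @param k Number of key lncRNAs to return (default 3).
#' @return Character vector of lncRNA ids, best first. If fewer than `k`
#'   lncRNAs are available, all are returned with a warning.
#' @export
rank_key_lncrnas <- function(pair_tbl, hubs = NULL, k = 3) {
  pair_tbl <- as_tibble(pair_tbl)
  if (!all(c("lnc_id", "n_first") %in% names(pair_tbl))) {
    abort("`pair_tbl` needs columns lnc_id and n_first")
  }
  if (!"total" %in% names(pair_tbl)) {
    pair_tbl$total <- pair_tbl$n_first + pair_tbl$n_second
  }
  if (!is.null(hubs)) {
    keep <- hubs$node_id[hubs$type == "lnc"]
    pair_tbl <- pair_tbl[pair_tbl$lnc_id %in% keep, ]
  }
  ranked <- arrange(pair_tbl, desc(.data$n_first), desc(.data$total),
                    .data$lnc_id)
  if (k > nrow(ranked)) {
    warn(sprintf("only %d lncRNAs available; returning all", nrow(ranked)))
    k <- nrow(ranked)
  }
  ranked$lnc_id[seq_len(k)]
}

#' Extract the subnetwork anchored at one lncRNA
#'
#' Induces the subgraph on the lncRNA, its partner miRNAs, and the mRNAs
#' adjacent to those miRNAs, keeping only the anchor's lnc-mi edges and the
#' selected miRNAs' mi-m edges. Its edge count equals the [pair_counts()]
#' `total` for that lncRNA.
#'
#' @param graph A [build_graph()] result.
#' @param lnc_id The anchor lncRNA id (must be a lnc-type node).
#' @return A `cerna_graph` subnetwork.
#' @export
extract_subnetwork <- function(graph, lnc_id) {
  types <- igraph::vertex_attr(graph, "type")
  names(types) <- igraph::V(graph)$name
  if (!lnc_id %in% names(types) || types[[lnc_id]] != "lnc") {
    abort(sprintf("unknown lncRNA node: %s", lnc_id))
  }
  mis <- igraph::neighbors(graph, lnc_id)$name
  mis <- mis[types[mis] == "mi"]
  ms <- unique(unlist(lapply(mis, function(u) {
    nb <- igraph::neighbors(graph, u)$name
    nb[types[nb] == "m"]
  })))
  keep <- c(lnc_id, mis, ms)
  sub <- igraph::induced_subgraph(graph, keep)
  # induced subgraph may carry lnc-mi edges of other lncRNAs only if those
  # lncRNAs were kept; they are not, so the edge set is already correct
  class(sub) <- c("cerna_graph", class(sub))
  sub
}
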