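#' Read and write expression tables
#'
#' Expression is stored as a TSV whose header row carries sample ids, with
#' two metadata columns (`transcript_id`, `type` in {lnc, mi, m}), plus a
#' sidecar TSV mapping `sample_id` to `group` in {case, control}.
#'
#' @param path,groups_path TSV paths.
#' @return `read_expression()`: list with `expr` and `groups` tibbles.
#' @export
read_expression <- function(path, groups_path) {
  expr <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", type = "c", .default = "d"), progress = FALSE)
  groups <- readr::read_tsv(groups_path, col_types = readr::cols(
    sample_id = "c", group = "c"), progress = FALSE)
  bad <- setdiff(unique(groups$group), c("case", "control"))
  if (length(bad)) {
    abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  }
  expr_matrix(expr, groups)  # validate
  list(expr = expr, groups = groups)
}

#' @rdname read_expression
#' @param expr,groups Tibbles as produced by [simulate_expression()].
#' @return `write_expression()`: `path`, invisibly.
#' @export
write_expression <- function(expr, groups, path, groups_path) {
  readr::write_tsv(expr, path, progress = FALSE)
  readr::write_tsv(groups, groups_path, progress = FALSE)
  invisible(path)
}

#' Read a FASTA file as a named character vector of RNA sequences
#'
#' @param path FASTA file; T is converted to U on read.
#' @return Named character vector, 5'->3'.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(set), normalize_rna, character(1))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of RNA sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Export a ceRNA graph
#'
#' `write_sif()` writes the simple interaction format
#' (`source<TAB>edge_type<TAB>target`, one edge per line); `write_graphml()`
#' writes GraphML with node attributes `type`, `fold_change`, `degree` —
#' both loadable by Cytoscape.
#'
#' @param graph A `cerna_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  et <- igraph::edge_attr(graph, "edge_type")
  lines <- sprintf("%s\t%s\t%s", el[, 1], et, el[, 2])
  writeLines(sort(lines), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(graph, path) {
  g <- graph
  igraph::V(g)$degree <- as.integer(igraph::degree(g))
  fc <- igraph::vertex_attr(g, "fold_change")
  if (!is.null(fc)) igraph::V(g)$fold_change <- ifelse(is.na(fc), 0, fc)
  class(g) <- setdiff(class(g), "cerna_graph")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
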