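#' Pearson correlation with t-transform p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` against Student's t with `n - 2`
#' degrees of freedom. `|r| = 1` gives `p = 0` exactly.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Tibble with one row: `pcc`, `p_value`, `n`. A constant vector
#'   yields `pcc = NA` (undefined, excluded downstream) with a warning.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(2, 4, 6))  # r = 1, p = 0
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("constant vector: correlation undefined")
    return(tibble(pcc = NA_real_, p_value = NA_real_, n = n))
  }
  r <- cor(x, y)
  p <- cor_pvalue(r, n)
  tibble(pcc = r, p_value = p, n = n)
}

# two-sided p from the t transform; |r| >= 1 -> 0
cor_pvalue <- function(r, n) {
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                     lower.tail = FALSE))
  pmin(p, 1)
}

#' Coexpressed lncRNA-mRNA pairs
#'
#' Computes Pearson correlations between every screened lncRNA and every
#' screened mRNA across all samples and keeps pairs with `pcc > pcc_cut` and
#' `p_value < p_cut` (both strict). The gate is one-sided on r — ceRNA
#' partners co-rise, so anticorrelated pairs are never coexpression
#' candidates.
#'
#' @param dels,dems Character vectors of lncRNA and mRNA ids (typically from
#'   [de_partition()]).
#' @param expr,groups Expression tibble and sample sheet as in [screen_de()].
#' @param pcc_cut,p_cut Correlation and significance gates (defaults 0.99,
#'   0.05).
#' @return Tibble: `lnc_id`, `m_id`, `pcc`, `p_value`, `n`, ordered by
#'   descending `pcc`.
#' @export
coexpression_pairs <- function(dels, dems, expr, groups,
                               pcc_cut = 0.99, p_cut = 0.05) {
  assert_scalar_number(pcc_cut, "pcc_cut", -1, 1)
  assert_scalar_number(p_cut, "p_cut", 0, 1)
  m <- expr_matrix(expr, groups)
  missing <- setdiff(c(dels, dems), rownames(m))
  if (length(missing)) {
    abort(sprintf("ids missing from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  empty <- tibble(lnc_id = character(), m_id = character(),
                  pcc = numeric(), p_value = numeric(), n = integer())
  if (length(dels) == 0 || length(dems) == 0) return(empty)
  n <- ncol(m)
  # row-constant transcripts have undefined correlation; drop them up front
  sds_l <- apply(m[dels, , drop = FALSE], 1, stats::sd)
  sds_m <- apply(m[dems, , drop = FALSE], 1, stats::sd)
  dels <- dels[sds_l > 0]
  dems <- dems[sds_m > 0]
  if (length(dels) == 0 || length(dems) == 0) return(empty)
  rmat <- cor(t(m[dels, , drop = FALSE]), t(m[dems, , drop = FALSE]))
  idx <- which(rmat > pcc_cut, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  out <- tibble(lnc_id = dels[idx[, 1]], m_id = dems[idx[, 2]],
                pcc = rmat[idx], n = n)
  out$p_value <- cor_pvalue(out$pcc, n)
  out <- out[out$p_value < p_cut, c("lnc_id", "m_id", "pcc", "p_value", "n")]
  arrange(out, desc(.data$pcc), .data$lnc_id, .data$m_id)
}

#' Assemble competing ceRNA triplets
#'
#' A triplet (lncRNA L, miRNA u, mRNA M) is emitted when (L, M) is a
#' coexpressed pair, u targets both L (predicted pairs) and M (table pairs),
#' and u is negatively correlated with each partner across all samples.
#' Candidates are enumerated exhaustively; output order is deterministic
#' (lnc, mi, m lexicographic).
#'
#' @param coexpr Coexpressed pairs from [coexpression_pairs()].
#' @param lnc_targets miRNA-lncRNA pairs from [predict_lnc_targets()].
#' @param mrna_targets miRNA-mRNA pairs from [load_mirna_mrna_table()].
#' @param expr,groups Expression tibble and sample sheet.
#' @param demis Optional character vector of differentially expressed miRNA
#'   ids; when given, only these miRNAs can anchor a triplet.
#' @param neg_p_cut Optional p-value gate on the two negative correlations
#'   (`NULL`, the default, gates only the sign, matching the convention that
#'   only the lncRNA-mRNA pair carries a significance gate).
#' @return A `cerna_triplets` tibble: `lnc_id`, `mi_id`, `m_id`,
#'   `lnc_m_pcc`, `mi_lnc_pcc`, `mi_m_pcc`.
#' @export
assemble_triplets <- function(coexpr, lnc_targets, mrna_targets, expr, groups,
                              demis = NULL, neg_p_cut = NULL) {
  m <- expr_matrix(expr, groups)
  n <- ncol(m)
  lt <- lnc_targets[, c("mirna_id", "target_id")]
  mt <- mrna_targets[, c("mirna_id", "target_id")]
  if (!is.null(demis)) {
    lt <- lt[lt$mirna_id %in% demis, ]
    mt <- mt[mt$mirna_id %in% demis, ]
  }
  out <- list()
  for (i in seq_len(nrow(coexpr))) {
    L <- coexpr$lnc_id[i]
    M <- coexpr$m_id[i]
    shared <- intersect(lt$mirna_id[lt$target_id == L],
                        mt$mirna_id[mt$target_id == M])
    for (u in shared) {
      if (!all(c(L, u, M) %in% rownames(m))) next
      r_ul <- cor(m[u, ], m[L, ])
      r_um <- cor(m[u, ], m[M, ])
      if (is.na(r_ul) || is.na(r_um)) next
      if (r_ul >= 0 || r_um >= 0) next
      if (!is.null(neg_p_cut) &&
          (cor_pvalue(r_ul, n) >= neg_p_cut ||
           cor_pvalue(r_um, n) >= neg_p_cut)) next
      out[[length(out) + 1L]] <- tibble(
        lnc_id = L, mi_id = u, m_id = M,
        lnc_m_pcc = coexpr$pcc[i], mi_lnc_pcc = r_ul, mi_m_pcc = r_um)
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(lnc_id = character(), mi_id = character(), m_id = character(),
           lnc_m_pcc = numeric(), mi_lnc_pcc = numeric(), mi_m_pcc = numeric())
  res <- arrange(distinct(res), .data$lnc_id, .data$mi_id, .data$m_id)
  new_tibble_class(res, "cerna_triplets")
}

#' Build the tripartite ceRNA graph from triplets
#'
#' Takes the union of the two edges (lnc-mi, mi-m) contributed by every
#' triplet, de-duplicated into a simple undirected graph. Nodes carry `type`
#' (`lnc`/`mi`/`m`) and, when a screen is supplied, `fold_change`; edges carry
#' `edge_type` (`"lnc-mi"` or `"mi-m"`). lncRNA-mRNA edges never occur —
#' interactions flow through miRNAs.
#'
#' @param triplets Triplet tibble from [assemble_triplets()].
#' @param screen Optional [screen_de()] result supplying node fold changes.
#' @return A `cerna_graph` (an igraph object with node/edge attributes).
#' @export
build_graph <- function(triplets, screen = NULL) {
  nodes <- bind_rows(
    tibble(name = unique(triplets$lnc_id), type = "lnc"),
    tibble(name = unique(triplets$mi_id), type = "mi"),
    tibble(name = unique(triplets$m_id), type = "m"))
  if (anyDuplicated(nodes$name)) {
    abort("a transcript id appears under two types; triplet members must be distinct")
  }
  edges <- bind_rows(
    distinct(tibble(from = triplets$lnc_id, to = triplets$mi_id,
                    edge_type = "lnc-mi")),
    distinct(tibble(from = triplets$mi_id, to = triplets$m_id,
                    edge_type = "mi-m")))
  edges <- arrange(edges, .data$edge_type, .data$from, .data$to)
  nodes <- arrange(nodes, .data$type, .data$name)
  if (!is.null(screen)) {
    nodes <- left_join(nodes, screen[, c("transcript_id", "fold_change")],
                       by = c(name = "transcript_id"))
  } else {
    nodes$fold_change <- NA_real_
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  class(g) <- c("cerna_graph", class(g))
  g
}
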