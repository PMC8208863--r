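#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the one-sided Fisher exact
#' p-value for drawing `k` or more annotated genes in a query of size `n`
#' from a universe of `N` genes of which `K` carry the annotation. Computed
#' via the stable distribution-function routine, exact for `N` well beyond
#' 1e5.
#'
#' @param k Overlap count (query genes in the set).
#' @param n Query size.
#' @param K Set size in the universe.
#' @param N Universe size.
#' @return The p-value; `k = 0` gives exactly 1.
#' @export
#' @examples
#' hypergeom_upper(2, 3, 4, 10)  # 40/120
hypergeom_upper <- function(k, n, K, N) {
  for (v in list(k = k, n = n, K = K, N = N)) {
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      abort("k, n, K, N must be single non-negative integers")
    }
  }
  if (k > n || n > N || K > N || k > K) {
    abort(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, elementwise `>= p` and order-preserving.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, tab-separated member genes).
#' @param category Category assigned to every term (`"BP"`, `"MF"`, `"CC"`,
#'   `"pathway"`), or `NA` to leave unset. Term lines whose description field
#'   is one of those labels take it from the file instead.
#' @return Gene-set tibble: `term_id`, `name`, `category`, list-column
#'   `genes`.
#' @export
read_gmt <- function(path, category = NA_character_) {
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(lines, function(x) if (length(x) >= 2) x[2] else "",
                 character(1))
  names(desc) <- vapply(lines, `[`, character(1), 1)
  cats <- ifelse(desc[names(sets)] %in% c("BP", "MF", "CC", "pathway"),
                 desc[names(sets)], category)
  tibble(term_id = names(sets),
         name = unname(desc[names(sets)]),
         category = unname(cats),
         genes = unname(sets))
}

#' Write a gene-set tibble as GMT
#'
#' The description field stores the category when present, else the name.
#'
#' @param collection Gene-set tibble as from [read_gmt()] or
#'   [simulate_genesets()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- if ("category" %in% names(collection) &&
              !all(is.na(collection$category))) {
    collection$category
  } else if ("name" %in% names(collection)) collection$name else "NA"
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$term_id[i], desc[i], collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric test of each gene set against the query, after
#' restricting both to the background universe. Terms with zero overlap are
#' suppressed. Results are sorted by ascending p-value, ties broken by
#' descending enrichment factor then term id; `top_n` rows are kept per
#' category. BH q-values are computed within category across all tested
#' (overlapping) terms before the top-n cut.
#'
#' @param query_genes Character vector of query gene ids. Genes outside the
#'   universe are dropped with a warning.
#' @param collection Gene-set tibble (`term_id`, `name`, `category`, list
#'   column `genes`), e.g. from [read_gmt()] or [simulate_genesets()].
#' @param universe Background gene ids (typically all measured mRNAs).
#'   Defaults to the union of all set members and the query.
#' @param top_n Rows reported per category (default 30); `Inf` keeps all.
#' @param p_cut Threshold used for the per-category enriched-term totals
#'   reported in attribute `"category_totals"` (default 0.05, raw p).
#' @return A `cerna_enrichment` tibble: `term_id`, `name`, `category`, `k`,
#'   `n`, `K`, `N`, `enrichment_factor`, `p_value`, `bh_q`.
#' @export
enrich <- function(query_genes, collection, universe = NULL, top_n = 30,
                   p_cut = 0.05) {
  if (is.null(universe)) {
    universe <- unique(c(unlist(collection$genes), query_genes))
  }
  universe <- unique(universe)
  dropped <- setdiff(query_genes, universe)
  if (length(dropped)) {
    warn(sprintf("%d query gene(s) outside the universe dropped",
                 length(dropped)))
  }
  query <- unique(intersect(query_genes, universe))
  if (length(query) == 0) abort("empty query after restriction to universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    members <- intersect(collection$genes[[i]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    if (k == 0) return(NULL)
    tibble(term_id = collection$term_id[i],
           name = collection$name[i],
           category = collection$category[i],
           k = k, n = n, K = K, N = N,
           enrichment_factor = (k / n) / (K / N),
           p_value = hypergeom_upper(k, n, K, N))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  empty <- tibble(term_id = character(), name = character(),
                  category = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(),
                  enrichment_factor = numeric(), p_value = numeric(),
                  bh_q = numeric())
  if (length(rows) == 0) {
    return(new_tibble_class(empty, "cerna_enrichment"))
  }
  out <- bind_rows(rows)
  out <- out |>
    group_by(.data$category) |>
    mutate(bh_q = bh_adjust(.data$p_value)) |>
    ungroup() |>
    arrange(.data$p_value, desc(.data$enrichment_factor), .data$term_id)
  totals <- out |>
    group_by(.data$category) |>
    summarise(n_enriched = sum(.data$p_value < p_cut), .groups = "drop")
  if (is.finite(top_n)) {
    out <- out |>
      group_by(.data$category) |>
      slice_head(n = top_n) |>
      ungroup() |>
      arrange(.data$p_value, desc(.data$enrichment_factor), .data$term_id)
  }
  out <- new_tibble_class(out, "cerna_enrichment")
  attr(out, "category_totals") <- totals
  out
}
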