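#' Scan a transcript for canonical seed-match sites
#'
#' Reports every transcript position whose 7-nt window is the exact
#' Watson-Crick reverse complement (no G:U wobble) of the miRNA seed,
#' positions 2-8 (1-based, 5'->3'). Overlapping sites are all reported, in
#' ascending order of start. Coordinates are 1-based and inclusive on the
#' transcript's sense strand; `start` is the 5'-most matched nucleotide.
#'
#' @param mirna_seq miRNA sequence, 5'->3', length >= 8 (T is converted to U).
#' @param transcript_seq Transcript sequence, 5'->3'.
#' @return Tibble with columns `start`, `end` (= start + 6), `site_seq`,
#'   `seed_span` (always `"2-8"`).
#' @export
#' @examples
#' seed_scan("UGAGGUAGUAGGUUGUAUAGUU", "AAACUACCUCAAA")  # one site at 4
seed_scan <- function(mirna_seq, transcript_seq) {
  mirna_seq <- normalize_rna(mirna_seq, "miRNA sequence")
  transcript_seq <- normalize_rna(transcript_seq, "transcript sequence")
  if (nchar(mirna_seq) < 8) abort("miRNA must be at least 8 nt")
  if (nchar(transcript_seq) < 1) abort("transcript must be nonempty")
  site <- reverse_complement_rna(seed_of(mirna_seq))
  if (nchar(transcript_seq) < 7) {
    return(tibble(start = integer(), end = integer(),
                  site_seq = character(), seed_span = character()))
  }
  hits <- Biostrings::matchPattern(site,
                                   Biostrings::RNAString(transcript_seq))
  starts <- Biostrings::start(hits)
  tibble(start = as.integer(starts), end = as.integer(starts + 6L),
         site_seq = rep(site, length(starts)),
         seed_span = rep("2-8", length(starts)))
}

#' Energy parameters for the duplex hybridization model
#'
#' The model is a deliberately simple intermolecular-hybridization surrogate,
#' not a reimplementation of RNAhybrid/miRanda energy tables: helices
#' accumulate stacked-pair energies (each stack scored as the mean of its two
#' pairs' base energies) and interior loops/bulges pay an affine penalty;
#' intramolecular structure is ignored. Energies are kcal/mol-style numbers —
#' more negative is more stable.
#'
#' @param stack_gc,stack_au,stack_gu Base energy of a G:C, A:U, G:U pair
#'   inside a stack.
#' @param loop_open,loop_extend Affine penalty for a loop/bulge between two
#'   helices: `loop_open + loop_extend * (unpaired nucleotides)`.
#' @param allow_gu Permit G:U wobble pairs in the duplex (seed matching is
#'   always strict Watson-Crick regardless).
#' @param max_loop Maximum unpaired stretch per strand bridged by one loop.
#' @return A `duplex_params` list.
#' @export
duplex_params <- function(stack_gc = -3.0, stack_au = -2.0, stack_gu = -1.0,
                          loop_open = 4.0, loop_extend = 0.5,
                          allow_gu = TRUE, max_loop = 15L) {
  structure(list(stack_gc = stack_gc, stack_au = stack_au,
                 stack_gu = stack_gu, loop_open = loop_open,
                 loop_extend = loop_extend, allow_gu = allow_gu,
                 max_loop = as.integer(max_loop)),
            class = "duplex_params")
}

# pair energy lookup for one base from each strand; NA if unpairable
pair_energy <- function(a, b, params) {
  key <- paste0(a, b)
  e <- c(GC = params$stack_gc, CG = params$stack_gc,
         AU = params$stack_au, UA = params$stack_au)
  if (params$allow_gu) e <- c(e, GU = params$stack_gu, UG = params$stack_gu)
  unname(e[key])
}

#' Minimum hybridization free energy of a miRNA-target duplex
#'
#' Minimizes, over all antiparallel duplex alignments of the two strands, the
#' sum of stack energies minus loop penalties under [duplex_params()]. A
#' duplex with no pairs (or a single isolated pair, which has no stack)
#' scores 0; adding complementarity can only lower the score, so more
#' complementary sequences never score higher than strict sub-complements.
#'
#' @param mirna_seq miRNA sequence, 5'->3'.
#' @param site_context Target-site context window (transcript subsequence,
#'   5'->3').
#' @param params A [duplex_params()].
#' @return Minimum free energy (<= 0).
#' @export
#' @examples
#' duplex_mfe("GGGGCCCC", "GGGGCCCC")  # fully complementary GC 8-mer: -21
duplex_mfe <- function(mirna_seq, site_context, params = duplex_params()) {
  s1 <- normalize_rna(mirna_seq, "miRNA sequence")
  s2 <- normalize_rna(site_context, "site context")
  if (nchar(s1) == 0 || nchar(s2) == 0) abort("empty sequence")
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  # reverse the target so that both indices advance 5'->3' on the miRNA and
  # 3'->5' on the target — the antiparallel duplex geometry
  b <- rev(strsplit(s2, "", fixed = TRUE)[[1]])
  m <- length(a)
  n <- length(b)
  E <- outer(seq_len(m), seq_len(n),
             function(i, j) {
               pe <- pair_energy(a[i], b[j], params)
               ifelse(is.na(pe), NA_real_, pe)
             })
  cells <- which(!is.na(E), arr.ind = TRUE)
  if (nrow(cells) == 0) return(0)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  M <- matrix(NA_real_, m, n)
  best <- 0
  L <- params$max_loop
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]
    j <- cells[r, 2]
    v <- 0  # start a fresh duplex at this pair
    i_lo <- max(1L, i - 1L - L)
    j_lo <- max(1L, j - 1L - L)
    for (ip in i_lo:(i - 1L)) {
      if (ip < 1L || ip >= i) next
      for (jp in j_lo:(j - 1L)) {
        if (jp < 1L || jp >= j) next
        prev <- M[ip, jp]
        if (is.na(prev)) next
        gap_a <- i - ip - 1L
        gap_b <- j - jp - 1L
        cost <- if (gap_a == 0L && gap_b == 0L) {
          (E[ip, jp] + E[i, j]) / 2  # stack energy: mean of the two pairs
        } else {
          params$loop_open + params$loop_extend * (gap_a + gap_b)
        }
        v <- min(v, prev + cost)
      }
    }
    M[i, j] <- v
    if (v < best) best <- v
  }
  best
}

#' Predict miRNA-lncRNA target pairs by seed match and duplex energy
#'
#' Scans every lncRNA for canonical seed sites of every miRNA, scores each
#' site's duplex energy on a context window around it, and reports the pair
#' when at least one site exists and the best (minimum) site energy is
#' `<= mfe_cut`. The default cut of -12 kcal/mol is the score of the weakest
#' possible perfect-seed duplex under the default energy model (seven A:U
#' pairs, six stacks at -2), so by construction it retains every strict seed
#' match; tighten it to demand additional pairing beyond the seed, or pass
#' `mfe_cut = NULL` to disable the energy gate.
#'
#' @param mirna_seqs,lnc_seqs Named character vectors of RNA sequences
#'   (5'->3'), or paths to FASTA files (read via [read_fasta()]). Ids must not
#'   collide across the two sets.
#' @param mfe_cut Maximum accepted best-site energy (kcal/mol), or `NULL` for
#'   no energy gate.
#' @param flank Context nucleotides on each side of the 7-nt site used for
#'   energy scoring.
#' @param params A [duplex_params()].
#' @return Tibble of target pairs: `mirna_id`, `target_id`, `target_class`
#'   (`"lnc"`), `evidence` (`"predicted"`), `best_mfe`, `n_sites`. Per-site
#'   detail (`start`, `mfe`) is attached as attribute `"sites"`.
#' @export
predict_lnc_targets <- function(mirna_seqs, lnc_seqs, mfe_cut = -12,
                                flank = 11L, params = duplex_params()) {
  mirna_seqs <- as_seq_set(mirna_seqs)
  lnc_seqs <- as_seq_set(lnc_seqs)
  shared <- intersect(names(mirna_seqs), names(lnc_seqs))
  if (length(shared)) {
    abort(sprintf("id collision between miRNA and lncRNA sets: %s",
                  paste(shared, collapse = ", ")))
  }
  site_rows <- list()
  for (mi in names(mirna_seqs)) {
    for (ln in names(lnc_seqs)) {
      hits <- seed_scan(mirna_seqs[[mi]], lnc_seqs[[ln]])
      if (nrow(hits) == 0) next
      len <- nchar(lnc_seqs[[ln]])
      mfe <- vapply(hits$start, function(s) {
        ctx <- substr(lnc_seqs[[ln]], max(1L, s - flank),
                      min(len, s + 6L + flank))
        duplex_mfe(mirna_seqs[[mi]], ctx, params = params)
      }, numeric(1))
      site_rows[[length(site_rows) + 1L]] <-
        tibble(mirna_id = mi, transcript_id = ln,
               start = hits$start, mfe = mfe)
    }
  }
  empty <- tibble(mirna_id = character(), target_id = character(),
                  target_class = character(), evidence = character(),
                  best_mfe = numeric(), n_sites = integer())
  if (length(site_rows) == 0) {
    attr(empty, "sites") <- tibble(mirna_id = character(),
                                   transcript_id = character(),
                                   start = integer(), mfe = numeric())
    return(empty)
  }
  sites <- bind_rows(site_rows)
  pairs <- sites |>
    group_by(.data$mirna_id, .data$transcript_id) |>
    summarise(best_mfe = min(.data$mfe), n_sites = dplyr::n(),
              .groups = "drop") |>
    rename(target_id = "transcript_id") |>
    mutate(target_class = "lnc", evidence = "predicted") |>
    select("mirna_id", "target_id", "target_class", "evidence",
           "best_mfe", "n_sites") |>
    arrange(.data$mirna_id, .data$target_id)
  if (!is.null(mfe_cut)) {
    pairs <- pairs[pairs$best_mfe <= mfe_cut, ]
  }
  attr(pairs, "sites") <- sites
  pairs
}

#' Load a curated miRNA-mRNA interaction table
#'
#' Reads a tab-delimited export with columns `miRNA`, `mRNA`, `source`
#' (case-insensitive; `mirna_id`/`mrna_id` also accepted), de-duplicates
#' pairs, and unions provenance across sources.
#'
#' @param x Path to a TSV file, or a data frame already in memory.
#' @return Tibble of target pairs: `mirna_id`, `target_id`, `target_class`
#'   (`"m"`), `evidence` (`"table"`), `source` (`;`-joined labels),
#'   `n_sources`.
#' @export
load_mirna_mrna_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_tsv(x, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  }
  x <- as_tibble(x)
  nm <- tolower(names(x))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (!length(hit)) abort(sprintf("missing required column (one of: %s)",
                                    paste(cands, collapse = ", ")))
    hit[1]
  }
  mi_col <- pick(c("mirna", "mirna_id"))
  m_col <- pick(c("mrna", "mrna_id", "target", "gene"))
  src_col <- pick(c("source", "database"))
  tab <- tibble(mirna_id = as.character(x[[mi_col]]),
                target_id = as.character(x[[m_col]]),
                source = as.character(x[[src_col]]))
  bad <- which(is.na(tab$mirna_id) | is.na(tab$target_id) |
                 is.na(tab$source) | tab$mirna_id == "" |
                 tab$target_id == "" | tab$source == "")
  if (length(bad)) {
    abort(sprintf("malformed interaction rows (missing fields) at line(s): %s",
                  paste(bad + 1L, collapse = ", ")))  # +1 for the header
  }
  tab |>
    distinct() |>
    group_by(.data$mirna_id, .data$target_id) |>
    summarise(n_sources = length(unique(.data$source)),
              source = paste(sort(unique(.data$source)), collapse = ";"),
              .groups = "drop") |>
    mutate(target_class = "m", evidence = "table") |>
    select("mirna_id", "target_id", "target_class", "evidence",
           "source", "n_sources") |>
    arrange(.data$mirna_id, .data$target_id)
}

# named character vector, or FASTA path
as_seq_set <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- read_fasta(x)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("sequences must be a named character vector or a FASTA path")
  }
  if (anyDuplicated(names(x))) abort("duplicate sequence ids")
  vapply(x, normalize_rna, character(1))
}
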