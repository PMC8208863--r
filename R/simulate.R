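#' Configure a synthetic ceRNA study
#'
#' Defines the generating conditions for a synthetic case/control expression
#' study with planted ceRNA structure: differentially expressed transcripts,
#' competing triplets in which a shared per-sample latent factor enters the
#' miRNA with one sign and its lncRNA/mRNA partners with the opposite sign,
#' seed sites planted in lncRNA sequences, and gene sets over-populated with
#' triplet mRNAs.
#'
#' Expression is simulated on the log2 scale with Gaussian noise, matching
#' microarray convention; fold changes are taken on the linear scale after
#' back-transform. Within a planted triplet the expected Pearson correlation
#' between coupled transcripts is `coupling^2 / (coupling^2 + noise_sd^2)`
#' (in absolute value), which the defaults place at ~0.997 — the regime the
#' conventional r > 0.99 coexpression gate presumes.
#'
#' @param n_case,n_control Samples per group.
#' @param n_lnc,n_mi,n_m Transcripts per class (lncRNA, miRNA, mRNA).
#' @param n_triplets Number of planted competing triplets. Triplet members are
#'   pairwise distinct and triplets share no transcripts.
#' @param fc_planted Linear fold change planted for DE transcripts (>= 1;
#'   1 means no differential signal, useful for null calibration).
#' @param coupling Latent-factor loading in `[0, 1]` controlling within-triplet
#'   correlations; 0 removes all triplet structure.
#' @param noise_sd Per-observation Gaussian noise standard deviation (log2
#'   units, > 0).
#' @param seed Integer seed; every generator sub-stream is derived from it, so
#'   a fixed config reproduces byte-identical outputs.
#' @param n_terms Gene sets to emit; `n_enriched` of them are planted enriched.
#' @param n_enriched Number of planted enriched terms (<= `n_terms`).
#' @param boost Sampling-weight multiplier for triplet mRNAs inside planted
#'   enriched terms (1 = no enrichment).
#' @param site_length Context window length (nt) around a planted seed site,
#'   used downstream when extracting duplex contexts.
#' @param n_de_decoys Per class, differentially expressed transcripts planted
#'   outside any triplet (capped at the transcripts left over in the class).
#' @param n_interaction_decoys Random non-planted miRNA-mRNA rows added to the
#'   simulated interaction table.
#' @param lnc_length lncRNA sequence length (nt, >= 200 per the lncRNA
#'   definition).
#' @param mi_len_range Range of miRNA lengths (nt), within 19-24.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_case = 5, n_control = 5, n_triplets = 2,
#'                   n_lnc = 6, n_mi = 6, n_m = 10, seed = 1)
sim_config <- function(n_case = 30, n_control = 30,
                       n_lnc = 60, n_mi = 30, n_m = 80,
                       n_triplets = 20,
                       fc_planted = 4,
                       coupling = 0.95,
                       noise_sd = 0.05,
                       seed = 1,
                       n_terms = 50,
                       n_enriched = 5,
                       boost = 10,
                       site_length = 30,
                       n_de_decoys = 10,
                       n_interaction_decoys = 40,
                       lnc_length = 300,
                       mi_len_range = c(19L, 24L)) {
  for (nm in c("n_case", "n_control", "n_lnc", "n_mi", "n_m", "n_triplets")) {
    assert_scalar_number(get(nm), nm, lower = 1)
  }
  assert_scalar_number(fc_planted, "fc_planted", lower = 1)
  assert_scalar_number(coupling, "coupling", lower = 0, upper = 1)
  assert_scalar_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0")
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_terms, "n_terms", lower = 1)
  if (n_enriched > n_terms) abort("`n_enriched` cannot exceed `n_terms`")
  if (lnc_length < 200) abort("`lnc_length` must be >= 200 nt (lncRNA definition)")
  if (min(mi_len_range) < 19 || max(mi_len_range) > 24) {
    abort("`mi_len_range` must lie within 19-24 nt")
  }
  too_small <- c(n_lnc, n_mi, n_m) < n_triplets
  if (any(too_small)) {
    abort(sprintf(
      "class counts (lnc=%d, mi=%d, m=%d) too small to host %d planted triplets",
      n_lnc, n_mi, n_m, n_triplets))
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_lnc = as.integer(n_lnc), n_mi = as.integer(n_mi), n_m = as.integer(n_m),
    n_triplets = as.integer(n_triplets),
    fc_planted = fc_planted, coupling = coupling, noise_sd = noise_sd,
    seed = as.integer(seed),
    n_terms = as.integer(n_terms), n_enriched = as.integer(n_enriched),
    boost = boost, site_length = as.integer(site_length),
    n_de_decoys = as.integer(n_de_decoys),
    n_interaction_decoys = as.integer(n_interaction_decoys),
    lnc_length = as.integer(lnc_length),
    mi_len_range = as.integer(mi_len_range)
  ), class = "sim_config")
}

sim_ids <- function(config) {
  list(
    lnc = sprintf("lnc-%03d", seq_len(config$n_lnc)),
    mi  = sprintf("mir-%03d", seq_len(config$n_mi)),
    m   = sprintf("mrna-%03d", seq_len(config$n_m))
  )
}

#' Simulate an expression matrix with planted ceRNA structure
#'
#' For each planted triplet a per-sample latent factor enters the miRNA row
#' with loading `-coupling` and the lncRNA/mRNA rows with `+coupling`, so in
#' expectation r(lnc, mRNA) > 0 while r(miRNA, lnc) < 0 and r(miRNA, mRNA) < 0.
#' Planted DE transcripts receive a `log2(fc_planted)` case-group shift; within
#' a triplet the miRNA shifts opposite to its partners (miRNA down, targets
#' up, or vice versa), the ceRNA expectation. All other transcripts are
#' exchangeable Gaussian noise around a per-transcript baseline.
#'
#' @param config A [sim_config()].
#' @return A list with `expr` (tibble: `transcript_id`, `type`, one column per
#'   sample; log2 values), `groups` (tibble: `sample_id`, `group`), and `truth`
#'   (ground-truth ledger: `planted_triplets`, `planted_de`, `planted_sites`,
#'   `enriched_terms`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sim_ids(config)
  n_s <- config$n_case + config$n_control
  sample_ids <- c(sprintf("case_%02d", seq_len(config$n_case)),
                  sprintf("ctrl_%02d", seq_len(config$n_control)))
  groups <- tibble(
    sample_id = sample_ids,
    group = rep(c("case", "control"), c(config$n_case, config$n_control))
  )
  is_case <- groups$group == "case"

  tr <- tibble(
    transcript_id = c(ids$lnc, ids$mi, ids$m),
    type = rep(c("lnc", "mi", "m"), c(config$n_lnc, config$n_mi, config$n_m))
  )
  n_t <- nrow(tr)
  baseline <- runif(n_t, 4, 12)
  mat <- matrix(rnorm(n_t * n_s, sd = config$noise_sd), n_t, n_s,
                dimnames = list(tr$transcript_id, sample_ids))
  mat <- mat + baseline

  k <- config$n_triplets
  triplets <- tibble(lnc_id = ids$lnc[seq_len(k)],
                     mi_id  = ids$mi[seq_len(k)],
                     m_id   = ids$m[seq_len(k)])
  ldelta <- log2(config$fc_planted)
  trip_dir <- sample(c(1, -1), k, replace = TRUE)
  for (j in seq_len(k)) {
    z <- rnorm(n_s)
    rows_up <- c(triplets$lnc_id[j], triplets$m_id[j])
    mat[rows_up, ] <- mat[rows_up, , drop = FALSE] +
      rep(config$coupling * z, each = 2)
    mat[triplets$mi_id[j], ] <- mat[triplets$mi_id[j], ] - config$coupling * z
    # aligned DE: partners shift together, the miRNA opposite
    mat[rows_up, is_case] <- mat[rows_up, is_case, drop = FALSE] +
      trip_dir[j] * ldelta
    mat[triplets$mi_id[j], is_case] <-
      mat[triplets$mi_id[j], is_case] - trip_dir[j] * ldelta
  }

  planted_de <- bind_rows(
    tibble(transcript_id = triplets$lnc_id, type = "lnc",
           direction = trip_dir, role = "triplet"),
    tibble(transcript_id = triplets$mi_id, type = "mi",
           direction = -trip_dir, role = "triplet"),
    tibble(transcript_id = triplets$m_id, type = "m",
           direction = trip_dir, role = "triplet")
  )
  if (config$fc_planted > 1 && config$n_de_decoys > 0) {
    for (cls in c("lnc", "mi", "m")) {
      free <- setdiff(tr$transcript_id[tr$type == cls],
                      planted_de$transcript_id)
      n_d <- min(config$n_de_decoys, length(free))
      if (n_d == 0) next
      dec <- sample(free, n_d)
      d_dir <- sample(c(1, -1), n_d, replace = TRUE)
      mat[dec, is_case] <- mat[dec, is_case, drop = FALSE] +
        d_dir * ldelta
      planted_de <- bind_rows(planted_de,
        tibble(transcript_id = dec, type = cls, direction = d_dir,
               role = "decoy"))
    }
  }
  if (config$fc_planted == 1) {
    planted_de <- planted_de[0, ]
  }

  # seed-site positions, fixed here so sequence emission is a pure embedding
  max_start <- config$lnc_length - config$site_length
  planted_sites <- tibble(
    mi_id = triplets$mi_id,
    transcript_id = triplets$lnc_id,
    start = sample(seq(10L, max_start), k, replace = TRUE)
  )

  truth <- list(
    planted_triplets = triplets,
    planted_de = planted_de,
    planted_sites = planted_sites,
    enriched_terms = sprintf("TERM%04d", seq_len(config$n_enriched))
  )
  expr <- dplyr::bind_cols(tr, as_tibble(mat))
  list(expr = expr, groups = groups, truth = truth)
}

#' Simulate miRNA and lncRNA sequences with planted seed sites
#'
#' Emits RNA sequences 5'->3': miRNAs of 19-24 nt and lncRNAs of
#' `lnc_length` nt (>= 200). At each planted site the lncRNA carries the exact
#' reverse complement of the corresponding miRNA's positions 2-8; everything
#' else is uniform random background with no guaranteed sites.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth ledger from [simulate_expression()] (its
#'   `planted_sites` drive the embedding).
#' @return List with named character vectors `mirna` and `lnc`.
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$planted_sites)) abort("`truth` must list planted_sites")
  set.seed(config$seed + 1L)
  ids <- sim_ids(config)
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }
  mi_lens <- sample(seq(config$mi_len_range[1], config$mi_len_range[2]),
                    config$n_mi, replace = TRUE)
  mirna <- setNames(vapply(mi_lens, rand_seq, character(1)), ids$mi)
  lnc <- setNames(vapply(rep(config$lnc_length, config$n_lnc), rand_seq,
                         character(1)), ids$lnc)
  for (i in seq_len(nrow(truth$planted_sites))) {
    s <- truth$planted_sites[i, ]
    if (s$start + 6L > nchar(lnc[[s$transcript_id]])) {
      abort(sprintf("planted site at %d exceeds transcript %s length",
                    s$start, s$transcript_id))
    }
    site <- reverse_complement_rna(seed_of(mirna[[s$mi_id]]))
    substr(lnc[[s$transcript_id]], s$start, s$start + 6L) <- site
  }
  list(mirna = mirna, lnc = lnc)
}

#' Simulate a curated-style miRNA-mRNA interaction table
#'
#' Planted triplet (miRNA, mRNA) pairs are always present; decoy rows are drawn
#' uniformly from the remaining miRNA x mRNA combinations. Each row carries a
#' source label emulating a curated-database export, and some pairs appear
#' under both sources.
#'
#' @inheritParams simulate_sequences
#' @return Tibble with columns `mirna_id`, `mrna_id`, `source`.
#' @export
simulate_interactions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  ids <- sim_ids(config)
  planted <- truth$planted_triplets
  sources <- c("mirtarbase", "mirwalk")
  rows <- tibble(mirna_id = planted$mi_id, mrna_id = planted$m_id,
                 source = sample(sources, nrow(planted), replace = TRUE))
  all_pairs <- expand.grid(mirna_id = ids$mi, mrna_id = ids$m,
                           stringsAsFactors = FALSE)
  key <- paste(all_pairs$mirna_id, all_pairs$mrna_id)
  free <- all_pairs[!key %in% paste(rows$mirna_id, rows$mrna_id), ]
  n_d <- min(config$n_interaction_decoys, nrow(free))
  if (n_d > 0) {
    dec <- free[sample.int(nrow(free), n_d), ]
    dec$source <- sample(sources, n_d, replace = TRUE)
    rows <- bind_rows(rows, dec)
  }
  # a slice of pairs is reported by both databases, as real exports are
  dup <- rows[sample.int(nrow(rows), max(1L, nrow(rows) %/% 5L)), ]
  dup$source <- ifelse(dup$source == sources[1], sources[2], sources[1])
  as_tibble(bind_rows(rows, dup))
}

#' Simulate a gene-set collection with planted enriched terms
#'
#' Emits `n_terms` gene sets over the mRNA universe. Terms listed in
#' `truth$enriched_terms` sample triplet mRNAs with probability weight `boost`
#' relative to background genes; all other terms draw uniformly.
#'
#' @inheritParams simulate_sequences
#' @return Tibble with columns `term_id`, `name`, `category`
#'   (BP/MF/CC/pathway) and list-column `genes`.
#' @export
simulate_genesets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$enriched_terms)) abort("`truth` must list enriched_terms")
  if (config$n_terms < length(truth$enriched_terms)) {
    abort("n_terms is smaller than the number of planted enriched terms")
  }
  set.seed(config$seed + 2L)
  ids <- sim_ids(config)
  universe <- ids$m
  trip_m <- truth$planted_triplets$m_id
  term_ids <- sprintf("TERM%04d", seq_len(config$n_terms))
  categories <- sample(c("BP", "MF", "CC", "pathway"), config$n_terms,
                       replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
  sizes <- sample(seq(10L, min(40L, length(universe))), config$n_terms,
                  replace = TRUE)
  w_boost <- ifelse(universe %in% trip_m, config$boost, 1)
  genes <- lapply(seq_len(config$n_terms), function(i) {
    w <- if (term_ids[i] %in% truth$enriched_terms) w_boost else rep(1, length(universe))
    sort(sample(universe, sizes[i], prob = w))
  })
  tibble(term_id = term_ids,
         name = paste0("synthetic term ", seq_len(config$n_terms)),
         category = categories,
         genes = genes)
}

#' Simulate a complete synthetic ceRNA study
#'
#' Convenience wrapper running [simulate_expression()],
#' [simulate_sequences()], [simulate_interactions()] and
#' [simulate_genesets()] under one config.
#'
#' @param config A [sim_config()].
#' @return A `cerna_sim` list: `expr`, `groups`, `mirna_seqs`, `lnc_seqs`,
#'   `interactions`, `genesets`, `truth`, `config`.
#' @export
simulate_cerna <- function(config = sim_config()) {
  ex <- simulate_expression(config)
  seqs <- simulate_sequences(config, ex$truth)
  inter <- simulate_interactions(config, ex$truth)
  gs <- simulate_genesets(config, ex$truth)
  structure(list(expr = ex$expr, groups = ex$groups,
                 mirna_seqs = seqs$mirna, lnc_seqs = seqs$lnc,
                 interactions = inter, genesets = gs,
                 truth = ex$truth, config = config),
            class = "cerna_sim")
}
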