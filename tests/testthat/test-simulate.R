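test_that("generator is deterministic and conserves transcript counts", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_cerna(cfg)
  b <- simulate_cerna(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$lnc_seqs, b$lnc_seqs)
  expect_identical(a$mirna_seqs, b$mirna_seqs)
  expect_identical(a$genesets, b$genesets)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$expr), cfg$n_lnc + cfg$n_mi + cfg$n_m)
  expect_equal(sum(a$expr$type == "lnc"), cfg$n_lnc)
  expect_equal(sum(a$expr$type == "mi"), cfg$n_mi)
  expect_equal(sum(a$expr$type == "m"), cfg$n_m)
  # re-emitted FASTA is byte-identical
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(simulate_sequences(cfg, a$truth)$lnc, f1)
  write_fasta(simulate_sequences(cfg, a$truth)$lnc, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_triplets = 50, n_mi = 10), "too small")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(coupling = 1.2), "coupling")
  expect_error(sim_config(fc_planted = 0.5), "fc_planted")
  expect_error(sim_config(lnc_length = 150), "200")
  expect_error(sim_config(n_terms = 3, n_enriched = 5), "n_enriched")
})

test_that("planted triplets carry the (+,-,-) correlation sign pattern", {
  # >= 200 replicate triplets in one draw
  cfg <- sim_config(n_case = 30, n_control = 30, n_lnc = 200, n_mi = 200,
                    n_m = 200, n_triplets = 200, coupling = 0.95,
                    noise_sd = 0.1, fc_planted = 1, seed = 1)
  ex <- simulate_expression(cfg)
  m <- cernet:::expr_matrix(ex$expr, ex$groups)
  tri <- ex$truth$planted_triplets
  signs <- vapply(seq_len(nrow(tri)), function(j) {
    r_lm <- cor(m[tri$lnc_id[j], ], m[tri$m_id[j], ])
    r_ul <- cor(m[tri$mi_id[j], ], m[tri$lnc_id[j], ])
    r_um <- cor(m[tri$mi_id[j], ], m[tri$m_id[j], ])
    r_lm > 0 && r_ul < 0 && r_um < 0
  }, logical(1))
  expect_gte(mean(signs), 0.9)
  # and the analytic expected magnitude c^2/(c^2 + s^2)
  r_lm <- vapply(seq_len(nrow(tri)), function(j) {
    cor(m[tri$lnc_id[j], ], m[tri$m_id[j], ])
  }, numeric(1))
  expect_equal(mean(r_lm), 0.95^2 / (0.95^2 + 0.1^2), tolerance = 0.02)
})

test_that("zero coupling removes triplet correlation structure", {
  cfg <- sim_config(n_case = 30, n_control = 30, n_lnc = 100, n_mi = 100,
                    n_m = 100, n_triplets = 100, coupling = 0,
                    fc_planted = 1, seed = 2)
  ex <- simulate_expression(cfg)
  m <- cernet:::expr_matrix(ex$expr, ex$groups)
  tri <- ex$truth$planted_triplets
  r <- vapply(seq_len(nrow(tri)), function(j) {
    cor(m[tri$lnc_id[j], ], m[tri$m_id[j], ])
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.05)  # centred on zero
})

test_that("planted fold changes land near the configured value", {
  cfg <- sim_config(n_case = 20, n_control = 20, fc_planted = 4, seed = 3)
  ex <- simulate_expression(cfg)
  m <- cernet:::expr_matrix(ex$expr, ex$groups)
  case <- ex$groups$sample_id[ex$groups$group == "case"]
  ctrl <- ex$groups$sample_id[ex$groups$group == "control"]
  fc <- vapply(ex$truth$planted_de$transcript_id, function(id) {
    abs(fold_change(m[id, case], m[id, ctrl], scale = "log2"))
  }, numeric(1))
  expect_gte(mean(fc), 3)
  expect_lte(mean(fc), 5)
})

test_that("planted seed sites carry the exact seed reverse complement", {
  cfg <- tiny_config(seed = 11)
  ex <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, ex$truth)
  expect_true(all(nchar(seqs$mirna) >= 19 & nchar(seqs$mirna) <= 24))
  expect_true(all(nchar(seqs$lnc) >= 200))
  for (i in seq_len(nrow(ex$truth$planted_sites))) {
    s <- ex$truth$planted_sites[i, ]
    window <- substr(seqs$lnc[[s$transcript_id]], s$start, s$start + 6)
    mi <- strsplit(seqs$mirna[[s$mi_id]], "", fixed = TRUE)[[1]]
    expect_identical(window,
                     paste(ORACLE_COMP[rev(mi[2:8])], collapse = ""))
  }
  expect_error(simulate_sequences(cfg, list()), "planted_sites")
})

test_that("null generator calibrates the raw-p screen at alpha", {
  cfg <- sim_config(n_case = 20, n_control = 20, n_lnc = 250, n_mi = 250,
                    n_m = 250, n_triplets = 10, coupling = 0,
                    fc_planted = 1, seed = 4)
  ex <- simulate_expression(cfg)
  sc <- screen_de(ex$expr, ex$groups)
  expect_lt(abs(mean(sc$p_value < 0.05) - 0.05), 0.02)
  expect_equal(sum(sc$passes), 0)  # the FC gate removes everything under null
})

test_that("gene-set generator plants detectable enrichment only when boosted", {
  # null calibration: boost = 1 leaves planted terms indistinguishable
  trip_m <- sprintf("mrna-%03d", 1:20)
  null_ps <- c()
  alt_in_top_decile <- c()
  for (s in 1:15) {
    cfg0 <- sim_config(n_m = 1000, n_triplets = 20, n_lnc = 20, n_mi = 20,
                       n_terms = 50, n_enriched = 5, boost = 1, seed = s)
    truth <- list(planted_triplets = tibble::tibble(
      lnc_id = sprintf("lnc-%03d", 1:20), mi_id = sprintf("mir-%03d", 1:20),
      m_id = trip_m), enriched_terms = sprintf("TERM%04d", 1:5))
    gs0 <- simulate_genesets(cfg0, truth)
    e0 <- enrich(trip_m, gs0, universe = sprintf("mrna-%03d", 1:1000),
                 top_n = Inf)
    null_ps <- c(null_ps, e0$p_value[e0$term_id %in% truth$enriched_terms])

    cfg1 <- sim_config(n_m = 1000, n_triplets = 20, n_lnc = 20, n_mi = 20,
                       n_terms = 50, n_enriched = 5, boost = 10, seed = s)
    gs1 <- simulate_genesets(cfg1, truth)
    e1 <- enrich(trip_m, gs1, universe = sprintf("mrna-%03d", 1:1000),
                 top_n = Inf)
    rank_of <- match(truth$enriched_terms, e1$term_id)
    rank_of[is.na(rank_of)] <- 51L
    # the planted-term group (its median rank) sits in the top decile of
    # the 50 terms
    alt_in_top_decile <- c(alt_in_top_decile,
                           stats::median(rank_of) <= 5L)
  }
  # under the null the planted-term p-values look uniform (discreteness
  # pushes the upper-tail mean slightly above 1/2)
  expect_gt(mean(null_ps), 0.35)
  expect_lt(mean(null_ps), 0.8)
  expect_gt(min(null_ps), 0.001)
  # boosted: planted terms sit in the top decile of 50 terms
  expect_gte(mean(alt_in_top_decile), 0.9)
})

test_that("interaction table always contains the planted pairs", {
  cfg <- tiny_config(seed = 5)
  ex <- simulate_expression(cfg)
  tab <- simulate_interactions(cfg, ex$truth)
  planted <- paste(ex$truth$planted_triplets$mi_id,
                   ex$truth$planted_triplets$m_id)
  expect_true(all(planted %in% paste(tab$mirna_id, tab$mrna_id)))
  expect_true(all(tab$source %in% c("mirtarbase", "mirwalk")))
})
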