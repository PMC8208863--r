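test_that("seed_scan finds canonical sites at the right coordinates", {
  hits <- seed_scan("UGAGGUAGUAGGUUGUAUAGUU", "AAACUACCUCAAA")
  expect_equal(hits$start, 4L)
  expect_equal(hits$site_seq, "CUACCUC")
  # no complementary window -> empty
  expect_equal(nrow(seed_scan("UGAGGUAGUAGGUUGUAUAGUU",
                              "AAAAAAAAAAAAA")), 0L)
  # two concatenated site contexts -> exactly two sites
  ctx <- "AAACUACCUCAAA"
  hits2 <- seed_scan("UGAGGUAGUAGGUUGUAUAGUU", paste0(ctx, ctx))
  expect_equal(hits2$start, c(4L, 17L))
  # T is converted, bad letters are named
  expect_equal(seed_scan("TGAGGTAGTAGGTTGTATAGTT", "AAACTACCTCAAA")$start, 4L)
  expect_error(seed_scan("UGAGGUAGUAGGUUGUAUAGUU", "AAANCC"), "N")
  expect_error(seed_scan("UGAGGUA", "ACGU"), "at least 8")
})

test_that("seed_scan matches a brute-force window checker on random input", {
  set.seed(2024)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    mi <- random_rna(sample(19:24, 1))
    tr <- random_rna(sample(25:60, 1))
    if (i %% 2 == 0) {
      # embed a genuine site so positives are well represented
      pos <- sample(seq_len(nchar(tr) - 6), 1)
      site <- paste(ORACLE_COMP[rev(strsplit(mi, "")[[1]][2:8])],
                    collapse = "")
      substr(tr, pos, pos + 6) <- site
    }
    expect_identical(seed_scan(mi, tr)$start, oracle_seed_sites(mi, tr),
                     info = sprintf("case %d: %s vs %s", i, mi, tr))
  }
})

test_that("duplex energies match hand-evaluated helices", {
  expect_equal(duplex_mfe("GGGGCCCC", "GGGGCCCC"), -3 * 7)
  expect_equal(duplex_mfe("AAAAAAAA", "UUUUUUUU"), -2 * 7)
  # no pairable bases at all -> no duplex, zero energy
  expect_equal(duplex_mfe("AAAA", "AAAA"), 0)
  expect_equal(duplex_mfe("CCCC", "CCCC"), 0)
  # an isolated pair carries no stack energy
  expect_equal(duplex_mfe("A", "U"), 0)
  expect_error(duplex_mfe("", "ACGU"), "empty")
  # mixed helix: GC,GC,AU,AU pairs -> stacks -3, -2.5, -2
  expect_equal(duplex_mfe("GGAA", "UUCC"), -7.5)
})

test_that("duplex_mfe equals exhaustive alignment enumeration (lengths <= 10)", {
  set.seed(77)
  for (i in 1:60) {
    s1 <- random_rna(sample(4:10, 1))
    s2 <- random_rna(sample(4:10, 1))
    expect_equal(duplex_mfe(s1, s2), oracle_duplex_mfe(s1, s2),
                 info = paste(s1, s2))
  }
  # and with wobble disabled
  p <- duplex_params(allow_gu = FALSE)
  for (i in 1:20) {
    s1 <- random_rna(sample(4:9, 1))
    s2 <- random_rna(sample(4:9, 1))
    expect_equal(duplex_mfe(s1, s2, params = p),
                 oracle_duplex_mfe(s1, s2, params = p),
                 info = paste(s1, s2))
  }
})

test_that("duplex energy is symmetric and monotone under lost complementarity", {
  set.seed(5)
  p_wc <- duplex_params(allow_gu = FALSE)
  for (i in 1:25) {
    s <- random_rna(8)
    rc <- paste(ORACLE_COMP[rev(strsplit(s, "")[[1]])], collapse = "")
    full <- duplex_mfe(s, rc)
    # strand order cannot matter
    expect_equal(duplex_mfe(rc, s), full)
    # reversal+complement of both strands (Watson-Crick scoring)
    s_rc <- paste(ORACLE_COMP[rev(strsplit(s, "")[[1]])], collapse = "")
    t_rc <- paste(ORACLE_COMP[rev(strsplit(rc, "")[[1]])], collapse = "")
    expect_equal(duplex_mfe(s_rc, t_rc, params = p_wc),
                 duplex_mfe(s, rc, params = p_wc))
    # breaking one pair can never stabilise the duplex
    chars <- strsplit(rc, "")[[1]]
    pos <- sample(2:7, 1)
    chars[pos] <- setdiff(c("A", "C", "G", "U"), chars[pos])[1]
    expect_gte(duplex_mfe(s, paste(chars, collapse = "")) - 1e-9, full)
  }
})

test_that("predict_lnc_targets recovers planted pairs and honours the gate", {
  cfg <- tiny_config(seed = 13)
  ex <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, ex$truth)
  pairs <- predict_lnc_targets(seqs$mirna, seqs$lnc, mfe_cut = NULL)
  planted <- paste(ex$truth$planted_sites$mi_id,
                   ex$truth$planted_sites$transcript_id)
  expect_true(all(planted %in% paste(pairs$mirna_id, pairs$target_id)))
  # the default gate keeps every perfect seed match too
  pairs_def <- predict_lnc_targets(seqs$mirna, seqs$lnc)
  expect_true(all(planted %in%
                    paste(pairs_def$mirna_id, pairs_def$target_id)))
  # an unsatisfiable gate empties the output; tightening is monotone
  expect_equal(nrow(predict_lnc_targets(seqs$mirna, seqs$lnc,
                                        mfe_cut = -Inf)), 0L)
  loose <- predict_lnc_targets(seqs$mirna, seqs$lnc, mfe_cut = -5)
  tight <- predict_lnc_targets(seqs$mirna, seqs$lnc, mfe_cut = -14)
  expect_true(all(paste(tight$mirna_id, tight$target_id) %in%
                    paste(loose$mirna_id, loose$target_id)))
  # every reported pair has a seed site
  expect_true(all(pairs_def$n_sites >= 1))
  sites <- attr(pairs, "sites")
  for (i in sample(nrow(pairs), min(5, nrow(pairs)))) {
    found <- oracle_seed_sites(seqs$mirna[[pairs$mirna_id[i]]],
                               seqs$lnc[[pairs$target_id[i]]])
    expect_gte(length(found), 1)
  }
  expect_error(
    predict_lnc_targets(c(x = "ACGUACGUA"), c(x = paste(rep("A", 10),
                                                        collapse = ""))),
    "collision")
})

test_that("interaction tables load with de-duplication and provenance union", {
  tab <- tibble::tibble(
    miRNA = c("mir-1", "mir-1", "mir-2"),
    mRNA = c("g1", "g1", "g2"),
    source = c("mirtarbase", "mirwalk", "mirtarbase"))
  out <- load_mirna_mrna_table(tab)
  expect_equal(nrow(out), 2L)
  expect_equal(out$source[out$mirna_id == "mir-1"], "mirtarbase;mirwalk")
  expect_equal(out$n_sources[out$mirna_id == "mir-1"], 2L)
  # exact duplicate rows collapse
  out2 <- load_mirna_mrna_table(tab[c(1, 1, 3), ])
  expect_equal(nrow(out2), 2L)
  # empty file with header
  f <- tempfile(fileext = ".tsv")
  writeLines("miRNA\tmRNA\tsource", f)
  expect_equal(nrow(load_mirna_mrna_table(f)), 0L)
  # malformed rows are reported with line numbers
  writeLines(c("miRNA\tmRNA\tsource", "mir-1\tg1\tdb", "mir-2\t\tdb"), f)
  expect_error(load_mirna_mrna_table(f), "line")
  expect_error(load_mirna_mrna_table(tibble::tibble(a = 1)), "column")
})
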