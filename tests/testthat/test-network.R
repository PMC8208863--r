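test_that("pearson_cor handles exact and degenerate cases", {
  r <- pearson_cor(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$pcc, 1)
  expect_equal(r$p_value, 0)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2))$pcc, -1)
  expect_warning(nd <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(nd$pcc))
  expect_error(pearson_cor(1:3, 1:4), "equal length")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("correlation p-values track the exact permutation distribution", {
  set.seed(303)
  diffs <- c()
  for (i in 1:12) {
    x <- rnorm(7)
    y <- 0.5 * sample(c(0, 1), 1) * x + rnorm(7)
    p_t <- pearson_cor(x, y)$p_value
    p_perm <- oracle_perm_cor(x, y)  # all 5040 orderings
    diffs <- c(diffs, abs(p_t - p_perm))
  }
  # the t transform approximates the exact null well at n = 7
  expect_lt(max(diffs), 0.08)
  expect_lt(mean(diffs), 0.03)
})

test_that("coexpression gate is strict and one-sided", {
  groups <- tibble::tibble(sample_id = paste0("s", 1:10),
                           group = rep(c("case", "control"), each = 5))
  base <- sin(1:10) + (1:10) / 3
  noisy <- base + c(0.3, -0.25, 0.2, -0.3, 0.25, -0.2, 0.3, -0.25, 0.2, -0.3)
  anti <- -base
  expr <- tibble::tibble(
    transcript_id = c("L1", "L2", "L3", "M1"),
    type = c("lnc", "lnc", "lnc", "m"))
  expr <- dplyr::bind_cols(expr, stats::setNames(
    as.data.frame(rbind(base, noisy, anti, base)), groups$sample_id))
  # identical rows: r = 1, retained
  out <- coexpression_pairs(c("L1", "L2", "L3"), "M1", expr, groups)
  expect_equal(out$lnc_id, "L1")
  expect_equal(out$pcc, 1)
  # the noisy pair is below the strict 0.99 gate, the anticorrelated one is
  # excluded by one-sidedness even though |r| = 1
  r_noisy <- cor(noisy, base)
  expect_lt(r_noisy, 0.99)
  expect_false("L2" %in% out$lnc_id)
  expect_false("L3" %in% out$lnc_id)
  # but both appear when the gate is loosened below their r
  out2 <- coexpression_pairs(c("L1", "L2", "L3"), "M1", expr, groups,
                             pcc_cut = r_noisy - 0.01)
  expect_setequal(out2$lnc_id, c("L1", "L2"))
  expect_error(coexpression_pairs("nope", "M1", expr, groups), "missing")
})

test_that("planted coexpression pairs survive the 0.99 gate", {
  cfg <- study_config(seed = 21)
  ex <- simulate_expression(cfg)
  sc <- screen_de(ex$expr, ex$groups)
  part <- de_partition(sc)
  out <- coexpression_pairs(part$dels, part$dems, ex$expr, ex$groups)
  tri <- ex$truth$planted_triplets
  found <- paste(tri$lnc_id, tri$m_id) %in% paste(out$lnc_id, out$m_id)
  expect_gte(mean(found), 0.9)
})

test_that("triplet assembly applies the shared-miRNA and sign gates", {
  groups <- tibble::tibble(sample_id = paste0("s", 1:6),
                           group = rep(c("case", "control"), each = 3))
  up <- c(1, 2, 3, 4, 5, 6)
  down <- -up
  expr <- tibble::tibble(
    transcript_id = c("L", "U", "M", "U2"),
    type = c("lnc", "mi", "m", "mi"))
  expr <- dplyr::bind_cols(expr, stats::setNames(
    as.data.frame(rbind(up, down, up, up)), groups$sample_id))
  coexpr <- tibble::tibble(lnc_id = "L", m_id = "M", pcc = 1,
                           p_value = 0, n = 6L)
  lt <- tibble::tibble(mirna_id = c("U", "U2"), target_id = c("L", "L"))
  mt <- tibble::tibble(mirna_id = c("U", "U2"), target_id = c("M", "M"))
  out <- assemble_triplets(coexpr, lt, mt, expr, groups)
  # U is anticorrelated with both partners; U2 co-rises and is rejected
  expect_equal(nrow(out), 1L)
  expect_equal(out$lnc_id, "L")
  expect_equal(out$mi_id, "U")
  expect_lt(out$mi_lnc_pcc, 0)
  expect_lt(out$mi_m_pcc, 0)
  # no shared miRNA -> no triplet
  out2 <- assemble_triplets(coexpr, lt[1, ], mt[2, ], expr, groups)
  expect_equal(nrow(out2), 0L)
  # demis restriction removes the anchor
  out3 <- assemble_triplets(coexpr, lt, mt, expr, groups, demis = "U2")
  expect_equal(nrow(out3), 0L)
})

test_that("graph assembly de-duplicates edges and satisfies the handshake lemma", {
  one <- tibble::tibble(lnc_id = "L1", mi_id = "U1", m_id = "M1",
                        lnc_m_pcc = 1, mi_lnc_pcc = -1, mi_m_pcc = -1)
  g1 <- build_graph(one)
  expect_equal(igraph::vcount(g1), 3)
  expect_equal(igraph::ecount(g1), 2)
  # two triplets sharing the miRNA and lncRNA: 4 nodes, 3 edges
  two <- dplyr::bind_rows(one, dplyr::mutate(one, m_id = "M2"))
  g2 <- build_graph(two)
  expect_equal(igraph::vcount(g2), 4)
  expect_equal(igraph::ecount(g2), 3)
  # miRNA degree = distinct lnc partners + distinct m partners
  expect_equal(unname(igraph::degree(g2, "U1")), 3)
  # shuffled triplet input reproduces the identical graph
  cfg <- tiny_config(seed = 31)
  sim <- simulate_cerna(cfg)
  run <- run_pipeline(sim)
  tri <- run$triplets
  g <- build_graph(tri)
  gs <- build_graph(tri[sample(nrow(tri)), ])
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(gs))
  expect_identical(node_degrees(g), node_degrees(gs))
  # handshake lemma
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  # only lnc-mi and mi-m edge classes exist
  expect_setequal(unique(igraph::edge_attr(g, "edge_type")),
                  c("lnc-mi", "mi-m"))
})
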