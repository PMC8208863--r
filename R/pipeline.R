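#' Pipeline thresholds
#'
#' All gates surfaced in one place, defaulting to the conventional values of
#' the microarray ceRNA recipe: p < 0.05 and |FC| > 2 for the differential
#' screen, r > 0.99 (p < 0.05) for lncRNA-mRNA coexpression, hub degree >= 5,
#' top 30 enrichment rows, 3 key lncRNAs. `mfe_cut` defaults to the weakest
#' perfect-seed duplex score under the default energy model (see
#' [predict_lnc_targets()]).
#'
#' @param p_cut,fc_cut Differential-screen gates.
#' @param pcc_cut,coexpr_p_cut Coexpression gates.
#' @param mfe_cut Duplex energy gate for predicted lncRNA targets (`NULL`
#'   disables).
#' @param hub_threshold Minimum hub degree.
#' @param top_n Enrichment rows per category.
#' @param k_key Number of key lncRNAs.
#' @param scale Expression scale flag (`"log2"` or `"linear"`).
#' @param flank Context flank for duplex scoring (nt).
#' @return A `cerna_params` list.
#' @export
cerna_params <- function(p_cut = 0.05, fc_cut = 2, pcc_cut = 0.99,
                         coexpr_p_cut = 0.05, mfe_cut = -12,
                         hub_threshold = 5, top_n = 30, k_key = 3,
                         scale = "log2", flank = 11L) {
  structure(list(p_cut = p_cut, fc_cut = fc_cut, pcc_cut = pcc_cut,
                 coexpr_p_cut = coexpr_p_cut, mfe_cut = mfe_cut,
                 hub_threshold = hub_threshold, top_n = top_n,
                 k_key = k_key, scale = scale, flank = as.integer(flank)),
            class = "cerna_params")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), parent = e)
  })
}

#' Run the full ceRNA inference pipeline
#'
#' Executes screen -> targets -> coexpression -> triplets -> graph ->
#' topology (hubs, key lncRNAs, subnetworks) -> enrichment on one bundle of
#' inputs, optionally writing every intermediate table plus SIF/GraphML
#' exports and a JSON run manifest to `out_dir`. Output files use fixed
#' numeric formatting, so re-running an identical configuration reproduces
#' byte-identical files.
#'
#' @param data A `cerna_sim` from [simulate_cerna()], or a list with elements
#'   `expr`, `groups`, `mirna_seqs`, `lnc_seqs`, `interactions` and
#'   optionally `genesets` and `truth` (ground-truth ledger enabling recovery
#'   metrics in the summary).
#' @param params A [cerna_params()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A `cerna_run` list: `screen`, `partition`, `lnc_targets`,
#'   `mrna_targets`, `coexpr`, `triplets`, `graph`, `degrees`, `hubs`,
#'   `pair_counts`, `key_lncrnas`, `subnetworks`, `enrichment` (network-level
#'   plus one per key lncRNA, `NULL` when no gene sets were supplied),
#'   `summary`, `recovery` (when truth is available), `manifest`.
#' @export
run_pipeline <- function(data, params = cerna_params(), out_dir = NULL) {
  need <- c("expr", "groups", "mirna_seqs", "lnc_seqs", "interactions")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("`data` is missing element(s): %s",
                  paste(miss, collapse = ", ")))
  }
  screen <- with_stage("screen",
    screen_de(data$expr, data$groups, p_cut = params$p_cut,
              fc_cut = params$fc_cut, scale = params$scale))
  part <- de_partition(screen)

  lnc_targets <- with_stage("targets", {
    mi_seqs <- data$mirna_seqs[intersect(names(data$mirna_seqs), part$demis)]
    lnc_seqs <- data$lnc_seqs[intersect(names(data$lnc_seqs), part$dels)]
    predict_lnc_targets(mi_seqs, lnc_seqs, mfe_cut = params$mfe_cut,
                        flank = params$flank)
  })
  mrna_targets <- with_stage("targets", {
    tab <- load_mirna_mrna_table(data$interactions)
    tab[tab$mirna_id %in% part$demis & tab$target_id %in% part$dems, ]
  })

  coexpr <- with_stage("coexpression",
    coexpression_pairs(part$dels, part$dems, data$expr, data$groups,
                       pcc_cut = params$pcc_cut, p_cut = params$coexpr_p_cut))
  triplets <- with_stage("triplets",
    assemble_triplets(coexpr, lnc_targets, mrna_targets, data$expr,
                      data$groups, demis = part$demis))
  graph <- with_stage("graph", build_graph(triplets, screen = screen))
  degrees <- node_degrees(graph)
  hubs <- hub_nodes(degrees, threshold = params$hub_threshold)
  pc <- pair_counts(graph)
  key <- if (nrow(pc)) {
    rank_key_lncrnas(pc, k = min(params$k_key, nrow(pc)))
  } else character()
  subnets <- with_stage("subnetworks",
    setNames(lapply(key, function(L) extract_subnetwork(graph, L)), key))

  enr <- NULL
  if (is.null(data$genesets)) {
    warn("no gene sets supplied; enrichment skipped")
  } else if (igraph::ecount(graph) > 0) {
    enr <- with_stage("enrichment", {
      universe <- data$expr$transcript_id[data$expr$type == "m"]
      net_m <- igraph::V(graph)$name[
        igraph::vertex_attr(graph, "type") == "m"]
      res <- list(network = enrich(net_m, data$genesets,
                                   universe = universe,
                                   top_n = params$top_n))
      for (L in key) {
        sub_m <- igraph::V(subnets[[L]])$name[
          igraph::vertex_attr(subnets[[L]], "type") == "m"]
        if (length(sub_m)) {
          res[[L]] <- enrich(sub_m, data$genesets, universe = universe,
                             top_n = params$top_n)
        }
      }
      res
    })
  }

  summary <- dplyr::bind_cols(glance(screen), glance(graph),
                              tibble(n_coexpr_pairs = nrow(coexpr),
                                     n_triplets = nrow(triplets),
                                     n_hubs = nrow(hubs),
                                     n_key_lncrnas = length(key)))
  recovery <- if (!is.null(data$truth)) {
    recovery_metrics(data$truth, screen, lnc_targets, triplets)
  }
  manifest <- list(
    package = "cernet",
    version = as.character(utils::packageVersion("cernet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    params = unclass(params),
    config_hash = rlang::hash(list(unclass(params),
                                   data$expr, data$groups)),
    counts = as.list(summary))

  run <- structure(list(
    screen = screen, partition = part, lnc_targets = lnc_targets,
    mrna_targets = mrna_targets, coexpr = coexpr, triplets = triplets,
    graph = graph, degrees = degrees, hubs = hubs, pair_counts = pc,
    key_lncrnas = key, subnetworks = subnets, enrichment = enr,
    summary = summary, recovery = recovery, manifest = manifest),
    class = "cerna_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# planted-truth scoring of the screen, target prediction, and triplets
recovery_metrics <- function(truth, screen, lnc_targets, triplets) {
  de_true <- truth$planted_de$transcript_id
  called <- screen$transcript_id[screen$passes]
  de_recall <- if (length(de_true)) {
    mean(de_true %in% called)
  } else NA_real_
  nulls <- setdiff(screen$transcript_id, de_true)
  de_fpr <- if (length(nulls)) mean(nulls %in% called) else NA_real_

  pt <- truth$planted_triplets
  true_pairs <- paste(pt$mi_id, pt$lnc_id)
  pred_pairs <- paste(lnc_targets$mirna_id, lnc_targets$target_id)
  site_recall <- if (length(true_pairs)) {
    mean(true_pairs %in% pred_pairs)
  } else NA_real_

  true_tri <- paste(pt$lnc_id, pt$mi_id, pt$m_id)
  pred_tri <- paste(triplets$lnc_id, triplets$mi_id, triplets$m_id)
  tibble(de_recall = de_recall, de_fpr = de_fpr,
         target_pair_recall = site_recall,
         triplet_recall = if (length(true_tri)) mean(true_tri %in% pred_tri)
                          else NA_real_,
         triplet_precision = if (length(pred_tri))
           mean(pred_tri %in% true_tri) else NA_real_)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(as_tibble(run$screen), p("differential_screen.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$coexpr, p("coexpression_pairs.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(run$triplets), p("triplets.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$degrees, p("node_degrees.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(run$hubs), p("hub_nodes.tsv"), progress = FALSE)
  readr::write_tsv(run$pair_counts, p("pair_counts.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(run$lnc_targets), p("lnc_targets.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(run$mrna_targets), p("mrna_targets.tsv"),
                   progress = FALSE)
  writeLines(run$key_lncrnas, p("key_lncrnas.txt"))
  if (igraph::ecount(run$graph) > 0) {
    write_sif(run$graph, p("network.sif"))
    write_graphml(run$graph, p("network.graphml"))
  }
  for (L in names(run$subnetworks)) {
    write_sif(run$subnetworks[[L]], p(sprintf("subnetwork_%s.sif", L)))
    write_graphml(run$subnetworks[[L]],
                  p(sprintf("subnetwork_%s.graphml", L)))
  }
  if (!is.null(run$enrichment)) {
    for (scope in names(run$enrichment)) {
      readr::write_tsv(as_tibble(run$enrichment[[scope]]),
                       p(sprintf("enrichment_%s.tsv", scope)),
                       progress = FALSE)
    }
  }
  readr::write_tsv(run$summary, p("summary.tsv"), progress = FALSE)
  if (!is.null(run$recovery)) {
    readr::write_tsv(run$recovery, p("recovery.tsv"), progress = FALSE)
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the pipeline from a YAML configuration file
#'
#' The config lists input paths (`expression`, `groups`, `mirna_fasta`,
#' `lnc_fasta`, `interactions`, optional `genesets`), an optional `out_dir`,
#' and an optional `params` section whose keys override [cerna_params()]
#' defaults. Relative paths resolve against the config file's directory.
#'
#' @param path YAML config file.
#' @return A `cerna_run` (see [run_pipeline()]).
#' @export
run_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    if (is.null(f)) return(NULL)
    if (file.exists(f)) f else file.path(base, f)
  }
  for (f in c("expression", "groups", "mirna_fasta", "lnc_fasta",
              "interactions")) {
    if (is.null(cfg[[f]])) abort(sprintf("config is missing '%s'", f))
    if (!file.exists(resolve(cfg[[f]]))) {
      abort(sprintf("config input '%s' not found: %s", f, cfg[[f]]))
    }
  }
  ex <- read_expression(resolve(cfg$expression), resolve(cfg$groups))
  data <- list(
    expr = ex$expr, groups = ex$groups,
    mirna_seqs = read_fasta(resolve(cfg$mirna_fasta)),
    lnc_seqs = read_fasta(resolve(cfg$lnc_fasta)),
    interactions = resolve(cfg$interactions),
    genesets = if (!is.null(cfg$genesets)) read_gmt(resolve(cfg$genesets)))
  params <- do.call(cerna_params, cfg$params %||% list())
  run_pipeline(data, params = params, out_dir = cfg$out_dir)
}
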