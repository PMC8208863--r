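# shared small study configurations

tiny_config <- function(seed = 42, ...) {
  args <- modifyList(list(
    n_case = 10, n_control = 10, n_lnc = 12, n_mi = 8, n_m = 15,
    n_triplets = 5, n_terms = 12, n_enriched = 3, n_de_decoys = 3,
    n_interaction_decoys = 10, seed = seed), list(...))
  do.call(cernet::sim_config, args)
}

# the default study conditions (the recovery-benchmark regime)
study_config <- function(seed = 1, ...) {
  do.call(cernet::sim_config, modifyList(list(seed = seed), list(...)))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "cernet", mustWork = TRUE)
}

read_hub_fixture <- function() {
  readr::read_tsv(fixture_path("pcos_hub_degrees.tsv"),
                  col_types = "cicd", progress = FALSE)
}

read_pair_fixture <- function() {
  readr::read_tsv(fixture_path("pcos_pair_counts.tsv"),
                  col_types = "ciii", progress = FALSE)
}
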