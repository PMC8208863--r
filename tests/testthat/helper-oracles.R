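# Independent oracles. These deliberately avoid the package's code paths:
# plain window scans, exhaustive alignment/draw enumeration, permutation
# tests. They are slow and only run at tiny problem sizes.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A")

# every transcript start whose 7-nt window pairs antiparallel, Watson-Crick,
# with miRNA positions 2-8
oracle_seed_sites <- function(mirna, transcript) {
  mi <- strsplit(mirna, "", fixed = TRUE)[[1]]
  expected_window <- unname(ORACLE_COMP[rev(mi[2:8])])
  tr <- strsplit(transcript, "", fixed = TRUE)[[1]]
  n <- length(tr)
  if (n < 7) return(integer())
  hits <- integer()
  for (s in seq_len(n - 6)) {
    if (all(tr[s:(s + 6)] == expected_window)) hits <- c(hits, s)
  }
  hits
}

# exhaustive enumeration of every antiparallel duplex alignment (chain of
# pairable positions), scored with the same documented energy constants;
# no loop-length cap, so only valid for short sequences
oracle_duplex_mfe <- function(s1, s2, params = cernet::duplex_params()) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(s2, "", fixed = TRUE)[[1]])
  vals <- c(GC = params$stack_gc, CG = params$stack_gc,
            AU = params$stack_au, UA = params$stack_au)
  if (params$allow_gu) {
    vals <- c(vals, GU = params$stack_gu, UG = params$stack_gu)
  }
  pe <- function(x, y) {
    key <- paste0(x, y)
    if (key %in% names(vals)) vals[[key]] else NA_real_
  }
  m <- length(a)
  n <- length(b)
  cells <- NULL
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (!is.na(pe(a[i], b[j]))) cells <- rbind(cells, c(i, j))
  }
  if (is.null(cells)) return(0)
  best <- 0
  recurse <- function(li, lj, score) {
    if (score < best) best <<- score
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]
      j <- cells[r, 2]
      if (i <= li || j <= lj) next
      ga <- i - li - 1
      gb <- j - lj - 1
      cost <- if (ga == 0 && gb == 0) {
        (pe(a[li], b[lj]) + pe(a[i], b[j])) / 2
      } else {
        params$loop_open + params$loop_extend * (ga + gb)
      }
      recurse(i, j, score + cost)
    }
  }
  for (r in seq_len(nrow(cells))) recurse(cells[r, 1], cells[r, 2], 0)
  best
}

# exact two-group permutation p-value over all group relabelings,
# statistic = absolute mean difference
oracle_perm_ttest <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  picks <- combn(length(pooled), n1)
  stats <- apply(picks, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# exact permutation p-value for |r| over all orderings of y (n <= 7)
oracle_perm_cor <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- abs(cor(x, y))
  rs <- vapply(perms(y), function(p) abs(cor(x, p)), numeric(1))
  mean(rs >= obs - 1e-12)
}

# P(X >= k) by enumerating every size-n draw from an N-gene universe with K
# annotated genes
oracle_hyper_upper <- function(k, n, K, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= k)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
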