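# Internal sequence helpers. All sequences are RNA, 5'->3', alphabet ACGU;
# T is silently converted to U at entry points.

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

normalize_rna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(bad) > 0 && any(nzchar(bad))) {
    abort(sprintf("invalid character '%s' in %s (expected A/C/G/U or T)",
                  bad[nzchar(bad)][1], what))
  }
  x
}

reverse_complement_rna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(RNA_COMPLEMENT[chars])), collapse = "")
}

# miRNA seed: positions 2-8 (1-based, inclusive), the canonical 7-mer.
seed_of <- function(mirna_seq) substr(mirna_seq, 2L, 8L)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}
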