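#' Two-group t-test for one transcript
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` gives the
#' pooled-variance variant), two-sided. Degenerate conventions: if both groups
#' are constant and equal, `t = 0, p = 1`; if both are constant but unequal the
#' difference is infinitely significant relative to zero within-group variance,
#' reported as `p = 0` with a warning.
#'
#' @param values_case,values_control Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances (classic two-sample t-test)?
#' @return Named list with `t_stat` and `p_value`.
#' @export
#' @examples
#' t_test_two_group(c(5.1, 4.9, 5.0, 5.2), c(3.0, 3.1, 2.9, 3.0))
t_test_two_group <- function(values_case, values_control, var_equal = FALSE) {
  if (length(values_case) < 2 || length(values_control) < 2) {
    abort("each group needs at least 2 values")
  }
  v1 <- stats::var(values_case)
  v2 <- stats::var(values_control)
  if (v1 == 0 && v2 == 0) {
    if (mean(values_case) == mean(values_control)) {
      return(list(t_stat = 0, p_value = 1))
    }
    warn("both groups constant but unequal; p reported as 0")
    return(list(t_stat = sign(mean(values_case) - mean(values_control)) * Inf,
                p_value = 0))
  }
  fit <- t.test(values_case, values_control, var.equal = var_equal)
  list(t_stat = unname(fit$statistic), p_value = fit$p.value)
}

#' Signed linear fold change between groups
#'
#' Computes the linear case/control mean ratio `r` (log2 values are
#' back-transformed with `2^x` before averaging) and reports it with the
#' signed convention common in microarray tables: `r` when `r >= 1`,
#' `-1/r` when `r < 1`, so a halving prints as -2 rather than 0.5.
#'
#' @inheritParams t_test_two_group
#' @param scale `"log2"` (values are back-transformed first) or `"linear"`.
#' @return Signed linear fold change (single number).
#' @export
#' @examples
#' fold_change(c(8, 8), c(2, 2), scale = "linear")   # +4
#' fold_change(c(2, 2), c(8, 8), scale = "linear")   # -4
fold_change <- function(values_case, values_control, scale = c("log2", "linear")) {
  scale <- arg_match(scale)
  if (scale == "log2") {
    values_case <- 2^values_case
    values_control <- 2^values_control
  }
  m1 <- mean(values_case)
  m2 <- mean(values_control)
  if (m1 <= 0 || m2 <= 0) {
    abort("group means must be positive on the linear scale")
  }
  r <- m1 / m2
  if (r >= 1) r else -1 / r
}

#' Screen differentially expressed transcripts
#'
#' Applies the per-transcript t-test and signed fold change, passing a
#' transcript when `p_value < p_cut` and `|fold_change| > fc_cut` (both
#' strict). BH-adjusted q-values are reported for information only — the
#' screen itself gates on raw p, following the conventional microarray ceRNA
#' recipe.
#'
#' @param expr Expression tibble: columns `transcript_id`, `type`
#'   (`lnc`/`mi`/`m`), then one numeric column per sample.
#' @param groups Tibble with `sample_id`, `group` (`case`/`control`); every
#'   sample column of `expr` must appear, with >= 2 samples per group.
#' @param p_cut,fc_cut Significance and fold-change gates (defaults 0.05, 2).
#' @param scale Scale of the stored values, `"log2"` (default) or `"linear"`.
#' @param var_equal Passed to [t_test_two_group()].
#' @return A `cerna_screen` tibble: `transcript_id`, `type`, `fold_change`,
#'   `t_stat`, `p_value`, `bh_q`, `passes`, ordered as the input. The gates
#'   are stored as attributes `p_cut` and `fc_cut`.
#' @export
screen_de <- function(expr, groups, p_cut = 0.05, fc_cut = 2,
                      scale = c("log2", "linear"), var_equal = FALSE) {
  scale <- arg_match(scale)
  assert_scalar_number(p_cut, "p_cut", 0, 1)
  assert_scalar_number(fc_cut, "fc_cut", lower = 0)
  m <- expr_matrix(expr, groups)
  case_cols <- groups$sample_id[groups$group == "case"]
  ctrl_cols <- groups$sample_id[groups$group == "control"]
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    abort("need at least 2 samples per group")
  }
  res <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, case_cols]
    y <- m[i, ctrl_cols]
    tt <- t_test_two_group(x, y, var_equal = var_equal)
    c(fold_change = fold_change(x, y, scale = scale),
      t_stat = tt$t_stat, p_value = tt$p_value)
  })
  res <- as_tibble(do.call(rbind, res))
  out <- bind_cols(expr[, c("transcript_id", "type")], res)
  out$bh_q <- p.adjust(out$p_value, method = "BH")
  out$passes <- out$p_value < p_cut & abs(out$fold_change) > fc_cut
  out <- new_tibble_class(out, "cerna_screen")
  attr(out, "p_cut") <- p_cut
  attr(out, "fc_cut") <- fc_cut
  out
}

#' Passing transcript ids from a screen, by class
#'
#' @param screen A [screen_de()] result.
#' @return Named list with `dels` (lncRNAs), `demis` (miRNAs), `dems`
#'   (mRNAs): the transcript ids passing both gates, a disjoint type-pure
#'   partition.
#' @export
de_partition <- function(screen) {
  pass <- screen[screen$passes, ]
  list(dels = pass$transcript_id[pass$type == "lnc"],
       demis = pass$transcript_id[pass$type == "mi"],
       dems = pass$transcript_id[pass$type == "m"])
}

# expression tibble -> numeric matrix (rows named by transcript), validated
expr_matrix <- function(expr, groups = NULL) {
  need <- c("transcript_id", "type")
  if (!all(need %in% names(expr))) {
    abort("`expr` must have columns transcript_id and type")
  }
  if (anyDuplicated(expr$transcript_id)) {
    abort("duplicate transcript ids in expression table")
  }
  bad_type <- setdiff(unique(expr$type), c("lnc", "mi", "m"))
  if (length(bad_type)) {
    abort(sprintf("unknown transcript type(s): %s",
                  paste(bad_type, collapse = ", ")))
  }
  sample_cols <- setdiff(names(expr), need)
  m <- as.matrix(expr[, sample_cols])
  rownames(m) <- expr$transcript_id
  if (!is.null(groups)) {
    missing <- setdiff(groups$sample_id, colnames(m))
    if (length(missing)) {
      abort(sprintf("samples missing from expression table: %s",
                    paste(missing, collapse = ", ")))
    }
    m <- m[, groups$sample_id, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}

new_tibble_class <- function(x, cls) {
  class(x) <- unique(c(cls, class(tibble())))
  x
}
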