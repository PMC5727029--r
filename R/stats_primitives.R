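#' Shared statistical primitives
#'
#' Thin, convention-fixing wrappers around base R's exact tests, returning a
#' uniform (statistic, p_value, method) result. Conventions: a 2x2 table with
#' any zero margin is uninformative and gets p = 1; the two-sided binomial
#' p-value sums outcome probabilities at most the observed one; the Wilcoxon
#' rank-sum test is exact (full enumeration) when n1 + n2 <= 12 and there are
#' no ties, otherwise the normal approximation with tie correction is used.
#'
#' @name stats_primitives
NULL

#' @rdname stats_primitives
#' @param table a 2x2 matrix of non-negative counts.
#' @return list(statistic, p_value, method).
#' @export
fisher_exact <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(statistic = NA_real_, p_value = 1,
                method = "Fisher exact (degenerate margin)"))
  ft <- stats::fisher.test(table)
  list(statistic = unname(ft$estimate), p_value = ft$p.value,
       method = "Fisher exact two-sided")
}

#' @rdname stats_primitives
#' @param k successes, `n` trials, `p0` null success probability.
#' @param n,p0 see `k`.
#' @export
binomial_test <- function(k, n, p0) {
  stopifnot(k >= 0, n >= k, p0 >= 0, p0 <= 1)
  bt <- stats::binom.test(k, n, p = p0)
  list(statistic = k / n, p_value = as.numeric(bt$p.value),
       method = "exact binomial two-sided")
}

#' @rdname stats_primitives
#' @param x,y numeric samples.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample in wilcoxon_rank_sum")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "Wilcoxon rank-sum exact"
                else "Wilcoxon rank-sum normal approximation")
}

#' @rdname stats_primitives
#' @param p vector of p-values.
#' @return for `bh_fdr`, the Benjamini-Hochberg step-up adjusted values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  stats::p.adjust(p, method = "BH")
}
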