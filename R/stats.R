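#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value follows the
#' minimum-likelihood rule (sum of probabilities of all tables at most as
#' likely as the observed one). The reported odds ratio is the sample
#' cross-product ratio (a*d)/(b*c), with `Inf` permitted, not the
#' conditional MLE.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A `cerna_test` with `odds_ratio` extra.
#' @export
fisher_exact <- function(tab, alternative = c("two_sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("fisher_exact: need a 2x2 table")
  if (any(tab < 0)) stop("fisher_exact: negative cell")
  ft <- stats::fisher.test(tab, alternative = switch(alternative,
    two_sided = "two.sided", greater = "greater", less = "less"))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  test_result(statistic = tab[1, 1], p = ft$p.value,
              alternative = alternative, method = "fisher_exact",
              odds_ratio = or)
}

#' Hypergeometric enrichment (upper tail)
#'
#' p = P(X >= k) with X ~ Hypergeometric(universe, special, set_size):
#' the probability of drawing at least `k` special genes when `set_size`
#' genes are drawn from a universe containing `special` special genes.
#'
#' @param k observed special genes in the set.
#' @param set_size size of the drawn set.
#' @param special number of special genes in the universe.
#' @param universe universe size.
#' @return A `cerna_test`.
#' @export
hypergeom_enrichment <- function(k, set_size, special, universe) {
  if (k < 0 || k > min(set_size, special) || set_size > universe ||
      special > universe)
    stop("hypergeom_enrichment: inconsistent counts")
  p <- stats::phyper(k - 1, special, universe - special, set_size,
                     lower.tail = FALSE)
  test_result(statistic = k, p = p, alternative = "greater",
              method = "hypergeom_enrichment")
}

#' Pearson chi-square test on a 2xk table
#'
#' Yates continuity correction is applied to 2x2 tables by default and
#' never to larger tables.
#'
#' @param tab contingency table (matrix).
#' @param yates apply continuity correction (2x2 only).
#' @return A `cerna_test`.
#' @export
chisq_2xk <- function(tab, yates = all(dim(tab) == 2)) {
  tab <- as.matrix(tab)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0)) stop("chisq_2xk: zero expected count")
  ct <- suppressWarnings(
    stats::chisq.test(tab, correct = yates && all(dim(tab) == 2)))
  test_result(statistic = unname(ct$statistic), p = ct$p.value,
              alternative = "two_sided", method = "chisq",
              df = unname(ct$parameter))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration when both samples are small and untied; otherwise the
#' normal approximation with tie and continuity correction. Two constant
#' identical samples give p = 1.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A `cerna_test`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: empty group")
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && length(unique(c(x, y))) == 1L) {
    return(test_result(statistic = length(x) * length(y) / 2, p = 1,
                       alternative = alternative, method = "wilcoxon"))
  }
  exact <- !ties && (length(x) + length(y)) <= 10
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = switch(alternative, two_sided = "two.sided",
                               greater = "greater", less = "less"),
    exact = exact, correct = TRUE))
  test_result(statistic = unname(wt$statistic), p = wt$p.value,
              alternative = alternative, method = "wilcoxon")
}

#' Exact binomial test
#'
#' Two-sided p-values use the minimum-likelihood rule: the sum of
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param k successes.
#' @param n trials.
#' @param p0 null success probability, in (0,1).
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A `cerna_test`.
#' @export
binomial_test <- function(k, n, p0 = 0.5,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (p0 <= 0 || p0 >= 1) stop("binomial_test: p0 must lie in (0,1)")
  if (k < 0 || k > n) stop("binomial_test: need 0 <= k <= n")
  bt <- stats::binom.test(k, n, p0, alternative = switch(alternative,
    two_sided = "two.sided", greater = "greater", less = "less"))
  test_result(statistic = k, p = bt$p.value, alternative = alternative,
              method = "binomial")
}

#' Pearson correlation with t-distribution p-value
#'
#' Two-sided p from t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of
#' freedom; |r| = 1 yields p = 0.
#'
#' @param x,y numeric vectors of equal length, n >= 4, non-constant.
#' @return A `cerna_test` with extras `r` and `n`.
#' @export
pearson_corr <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("pearson_corr: length mismatch")
  if (n < 4) stop("pearson_corr: need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_corr: zero variance")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  test_result(statistic = r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps)),
              p = p, alternative = "two_sided", method = "pearson",
              r = r, n = n)
}

#' Multiple-testing adjustment
#'
#' @param pvec vector of raw p-values.
#' @param method `"bonferroni"` (min(1, m*p)) or `"bh"`
#'   (Benjamini-Hochberg step-up).
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvec, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!length(pvec)) stop("adjust_pvalues: empty vector")
  if (any(pvec < 0 | pvec > 1, na.rm = TRUE))
    stop("adjust_pvalues: p outside [0,1]")
  stats::p.adjust(pvec, method = switch(method, bonferroni = "bonferroni",
                                        bh = "BH"))
}

#' Add-one empirical p-value (upper tail)
#'
#' p = (1 + #\{null >= observed\}) / (1 + n_draws). Ties count toward the
#' tail; the add-one convention keeps p >= 1/(n+1).
#'
#' @param observed observed statistic.
#' @param null_draws vector of null statistics.
#' @return numeric p-value.
#' @export
empirical_p <- function(observed, null_draws) {
  if (!length(null_draws)) stop("empirical_p: need >= 1 null draw")
  (1 + sum(null_draws >= observed)) / (1 + length(null_draws))
}
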