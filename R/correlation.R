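#' Genome-wide lncRNA x coding expression correlations
#'
#' Computes Pearson r for every lncRNA-coding pair by blocked matrix
#' multiplication of standardized expression vectors, with two-sided
#' p-values from the t distribution on n-2 degrees of freedom and
#' Bonferroni correction over the full family of attempted pairs
#' (pairs dropped for zero variance still count toward the family size
#' `m_tested`). The result is identical for any block size.
#'
#' @param em an `expr_matrix` on the `adjusted` scale (the intended
#'   input; any log-scale matrix is accepted for comparative runs).
#' @param lnc_ids,coding_ids gene ids of the two classes (must be rows of
#'   `em`).
#' @param config an [analysis_config()]; supplies `corr_r_sig`.
#' @param block_size coding genes per block.
#' @param alpha significance level applied to the Bonferroni p.
#' @return list of class `corr_result`: `pairs` data.frame (`lnc_id`,
#'   `coding_id`, `r`, `p`, `p_bonf`, `significant`), `m_tested`, `n`,
#'   `dropped` (ids removed for zero variance).
#' @export
pairwise_correlations <- function(em, lnc_ids, coding_ids,
                                  config = analysis_config(),
                                  block_size = 512L, alpha = 0.05) {
  m <- em$values
  missing <- setdiff(c(lnc_ids, coding_ids), rownames(m))
  if (length(missing))
    stop("pairwise_correlations: genes absent from matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  n <- ncol(m)
  if (n < 4) stop("pairwise_correlations: need >= 4 samples")
  m_tested <- length(lnc_ids) * length(coding_ids)
  sds <- apply(m[c(lnc_ids, coding_ids), , drop = FALSE], 1, stats::sd)
  dropped <- names(sds)[sds == 0]
  if (length(dropped))
    message("pairwise_correlations: dropped for zero variance: ",
            length(dropped), " genes")
  lnc_ids <- setdiff(lnc_ids, dropped)
  coding_ids <- setdiff(coding_ids, dropped)
  z <- function(ids) {
    x <- m[ids, , drop = FALSE]
    x <- x - rowMeans(x)
    x / sqrt(rowSums(x^2))
  }
  zl <- z(lnc_ids)
  out <- vector("list", ceiling(length(coding_ids) / block_size))
  for (b in seq_along(out)) {
    idx <- ((b - 1) * block_size + 1):min(b * block_size,
                                          length(coding_ids))
    zc <- z(coding_ids[idx])
    r <- zl %*% t(zc)
    r[r > 1] <- 1; r[r < -1] <- -1
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
    out[[b]] <- data.frame(
      lnc_id = rep(lnc_ids, times = length(idx)),
      coding_id = rep(coding_ids[idx], each = length(lnc_ids)),
      r = as.vector(r), p = as.vector(p), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  pairs$p_bonf <- pmin(1, pairs$p * m_tested)
  pairs$significant <- abs(pairs$r) >= config$corr_r_sig &
    pairs$p_bonf < alpha
  res <- list(pairs = pairs, m_tested = m_tested, n = n, dropped = dropped,
              alpha = alpha, r_sig = config$corr_r_sig)
  class(res) <- "corr_result"
  res
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf(
    "corr_result: %d pairs (m_tested=%d, n=%d), %d significant at |r|>=%g\n",
    nrow(x$pairs), x$m_tested, x$n, sum(x$pairs$significant), x$r_sig))
  invisible(x)
}

#' Binomial test for the excess of positive significant correlations
#'
#' Two-sided exact binomial test of the number of positive correlations
#' among the significant lncRNA-coding pairs against p0 = 0.5.
#'
#' @param cr a `corr_result`.
#' @return A `cerna_test` with `positive_fraction` extra.
#' @export
positivity_test <- function(cr) {
  sig <- cr$pairs[cr$pairs$significant, , drop = FALSE]
  if (!nrow(sig)) stop("positivity_test: zero significant pairs")
  k <- sum(sig$r > 0)
  res <- binomial_test(k, nrow(sig), 0.5, "two_sided")
  res$positive_fraction <- k / nrow(sig)
  res
}

#' Are adjacent lncRNA-coding pairs more correlated than random pairs?
#'
#' Adjacent pairs overlap in gene body or have TSS distance below
#' `window`; an equal-count random sample of non-adjacent pairs is drawn
#' and the -log10 correlation-test p-values of the two sets are compared
#' by Wilcoxon rank-sum (greater).
#'
#' @param cr a `corr_result` covering the candidate pairs.
#' @param gt `gene_table` holding both gene classes.
#' @param window TSS distance threshold in bp.
#' @param n_random size of the random comparison set (default: same as
#'   adjacent count).
#' @param seed RNG seed for the random sample.
#' @param alternative Wilcoxon alternative (default two-sided).
#' @return A `cerna_test` with group sizes as extras.
#' @export
adjacency_correlation_test <- function(cr, gt, window = 100e3,
                                       n_random = NULL, seed = 1L,
                                       alternative = "two_sided") {
  pairs <- cr$pairs
  idx <- match(pairs$lnc_id, gt$gene_id)
  jdx <- match(pairs$coding_id, gt$gene_id)
  if (anyNA(idx) || anyNA(jdx))
    stop("adjacency_correlation_test: pair genes missing from annotation")
  same_chrom <- gt$chrom[idx] == gt$chrom[jdx]
  tss_d <- abs(gt$tss[idx] - gt$tss[jdx])
  overlap <- same_chrom & gt$start[idx] < gt$end[jdx] &
    gt$start[jdx] < gt$end[idx]
  adjacent <- overlap | (same_chrom & tss_d < window)
  if (!any(adjacent)) stop("adjacency_correlation_test: no adjacent pairs")
  if (is.null(n_random)) n_random <- sum(adjacent)
  pool <- which(!adjacent)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rand <- sample(pool, min(n_random, length(pool)))
  score <- -log10(pmax(pairs$p, 1e-320))
  res <- wilcoxon_rank_sum(score[adjacent], score[rand], alternative)
  res$n_adjacent <- sum(adjacent)
  res$n_random <- length(rand)
  res
}

#' Do pairs sharing miRNA binding sites correlate more strongly?
#'
#' Wilcoxon comparison (greater) of -log10 correlation-test p between
#' lncRNA-coding pairs that share at least one expressed bound miRNA and
#' pairs that share none.
#'
#' @param cr a `corr_result`.
#' @param lnc_bindings,mrna_bindings `interaction_table`s for the two
#'   target classes.
#' @param expressed_mirnas character vector of expressed miRNA ids.
#' @param alternative Wilcoxon alternative (default two-sided).
#' @return A `cerna_test` with group sizes as extras.
#' @export
shared_mirna_correlation_test <- function(cr, lnc_bindings, mrna_bindings,
                                          expressed_mirnas,
                                          alternative = "two_sided") {
  if (!nrow(lnc_bindings) || !nrow(mrna_bindings))
    stop("shared_mirna_correlation_test: binding tables empty")
  shared <- shared_mirna_map(lnc_bindings, mrna_bindings, expressed_mirnas)
  key <- paste(cr$pairs$lnc_id, cr$pairs$coding_id, sep = "\r")
  has_shared <- key %in% names(shared)
  if (all(has_shared) || !any(has_shared))
    stop("shared_mirna_correlation_test: one group empty")
  score <- -log10(pmax(cr$pairs$p, 1e-320))
  res <- wilcoxon_rank_sum(score[has_shared], score[!has_shared],
                           alternative)
  res$n_shared <- sum(has_shared)
  res$n_unshared <- sum(!has_shared)
  res
}

# internal: named list keyed by "lnc\rmrna" of shared expressed miRNA ids
shared_mirna_map <- function(lnc_bindings, mrna_bindings,
                             expressed_mirnas) {
  lb <- lnc_bindings[lnc_bindings$mirna_id %in% expressed_mirnas, ]
  mb <- mrna_bindings[mrna_bindings$mirna_id %in% expressed_mirnas, ]
  if (!nrow(lb) || !nrow(mb)) return(stats::setNames(list(), character()))
  merged <- merge(unique(lb[c("mirna_id", "target_id")]),
                  unique(mb[c("mirna_id", "target_id")]),
                  by = "mirna_id", suffixes = c("_lnc", "_mrna"))
  if (!nrow(merged)) return(stats::setNames(list(), character()))
  split(merged$mirna_id,
        paste(merged$target_id_lnc, merged$target_id_mrna, sep = "\r"))
}

#' Per-coding-gene counts of correlated lncRNAs, binned, DE vs non-DE
#'
#' Counts significantly correlated lncRNAs per coding gene, bins the
#' counts as none (0), few (1-10) and many (>10), and compares the bin
#' distribution between DE and non-DE coding genes by chi-square.
#'
#' @param cr a `corr_result`.
#' @param coding_ids coding gene universe.
#' @param coding_de logical DE flags along `coding_ids`.
#' @return list with `counts` (per-gene), `bin` factor, `table` (2x3) and
#'   `test`.
#' @export
correlated_lncrna_counts <- function(cr, coding_ids, coding_de) {
  sig <- cr$pairs[cr$pairs$significant, , drop = FALSE]
  cnt <- table(factor(sig$coding_id, levels = coding_ids))
  counts <- as.vector(cnt)
  bin <- cut(counts, breaks = c(-Inf, 0, 10, Inf),
             labels = c("none", "few", "many"))
  tab <- rbind(de = table(bin[coding_de]),
               non_de = table(bin[!coding_de]))
  keep <- colSums(tab) > 0
  list(counts = stats::setNames(counts, coding_ids), bin = bin, table = tab,
       test = chisq_2xk(tab[, keep, drop = FALSE], yates = FALSE))
}
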